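# shared fixtures, built in code at test time

the_schedule <- default_frame_schedule()
the_input <- simulate_input_function()   # deterministic (no seed -> no jitter)

# small cohort spec factory for fast end-to-end tests
small_spec <- function(n_patients = 3, n_controls = 0, cv = 0, seed = 101,
                       asym_sd = c(K1 = 0, k2 = 0, k3 = 0), jitter_sd = 0,
                       regions = c("A", "B"), ...) {
  cohort_spec(n_patients = n_patients, n_controls = n_controls, cv = cv,
              asym_sd = asym_sd, jitter_sd = jitter_sd,
              regions = regions, epi_weights = rep(1, length(regions)),
              rc = 0.8, sp = 0.2, amplitude_jitter_sd = 0.05,
              seed = seed, ...)
}

# independent brute-force enumeration of the two-sided rank-sum p-value
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  ctr <- n1 * (length(pooled) + 1) / 2
  cc <- utils::combn(length(pooled), n1)
  stats <- apply(cc, 2, function(idx) sum(r[idx]))
  mean(abs(stats - ctr) >= abs(obs - ctr) - 1e-9)
}

# independent brute-force enumeration of the two-sided signed-rank p-value
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  m <- length(d)
  ctr <- m * (m + 1) / 4
  stats <- vapply(seq_len(2^m) - 1, function(mask) {
    sum(r[bitwAnd(2^(seq_len(m) - 1), mask) > 0])
  }, numeric(1))
  mean(abs(stats - ctr) >= abs(obs - ctr) - 1e-9)
}
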