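#' Side-to-side asymmetry index
#'
#' `ASYM = (contralateral - ipsilateral) * 2 / (contralateral + ipsilateral)`.
#' Positive for a hypometabolic focus (ipsilateral value reduced). The
#' index is antisymmetric under side swap, bounded in [-2, 2] for
#' nonnegative inputs, and invariant to any common positive scaling of
#' both sides — which is what makes an uncalibrated image-derived input
#' function admissible upstream.
#'
#' @param contra contralateral value(s).
#' @param ipsi ipsilateral value(s).
#' @return signed unitless index, vectorized.
#' @examples
#' asym_index(1.25, 0.75)  # 0.5
#' @export
asym_index <- function(contra, ipsi) {
  n <- max(length(contra), length(ipsi))
  contra <- rep_len(contra, n); ipsi <- rep_len(ipsi, n)
  s <- contra + ipsi
  if (any(!is.finite(s))) stop("domain error: non-finite inputs")
  if (any(s == 0))
    stop("undefined-index error: contralateral + ipsilateral == 0")
  (contra - ipsi) * 2 / s
}

#' Build an asymmetry-record table
#'
#' Long-format table of per subject x region x parameter asymmetry
#' records from ipsilateral/contralateral value pairs.
#'
#' @param data data.frame with columns `subject_id`, `group`, `region_id`,
#'   `region_class` (`"epileptogenic"` / `"non_epileptogenic"`),
#'   `parameter` (one of K1, k2, k3, Ki, staticAC), `ipsi`, `contra`.
#' @return The input with `asym` and `abs_asym` columns appended.
#' @export
asym_table <- function(data) {
  need <- c("subject_id", "group", "region_id", "region_class",
            "parameter", "ipsi", "contra")
  if (!all(need %in% names(data)))
    stop("domain error: asym table needs columns ", paste(need, collapse = ", "))
  data$asym <- asym_index(data$contra, data$ipsi)
  data$abs_asym <- abs(data$asym)
  data
}

#' Mean absolute left/right asymmetry for one control subject
#'
#' Controls have no focus side, so their physiological asymmetry is
#' summarized as the absolute value of the left/right index averaged over
#' the configured evaluation regions, per parameter.
#'
#' @param records asymmetry-record rows for one subject (see
#'   [asym_table()]); the `asym` column may carry either sign convention
#'   since only `|asym|` is used.
#' @param region_ids the evaluation regions that must all be present.
#' @return named numeric vector: mean `|asym|` per parameter.
#' @export
control_mean_abs_asym <- function(records, region_ids) {
  by_par <- split(records, records$parameter)
  vapply(by_par, function(d) {
    miss <- setdiff(region_ids, d$region_id)
    if (length(miss) > 0)
      stop("incomplete-subject error: missing region(s) ",
           paste(miss, collapse = ", "))
    d <- d[d$region_id %in% region_ids, ]
    mean(abs(d$asym))
  }, numeric(1))
}

## ---- Wilcoxon rank tests --------------------------------------------------

rank_sum_enumeration <- function(a, b) {
  r <- rank(c(a, b))           # midranks under ties
  n1 <- length(a); N <- length(r)
  obs <- sum(r[seq_len(n1)])
  ctr <- n1 * (N + 1) / 2
  combs <- utils::combn(N, n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  p <- mean(abs(sums - ctr) >= abs(obs - ctr) - 1e-9)
  list(statistic = obs, p = p)
}

rank_sum_normal <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  v <- n1 * n2 * (N + 1) / 12 -
    n1 * n2 * sum(ties^3 - ties) / (12 * N * (N - 1))
  if (v <= 0) return(list(statistic = W, p = 1))
  z <- (W - mu) / sqrt(v)
  list(statistic = W, p = 2 * stats::pnorm(-abs(z)))
}

signed_rank_enumeration <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  ctr <- m * (m + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  sums <- as.vector(signs %*% r)
  p <- mean(abs(sums - ctr) >= abs(obs - ctr) - 1e-9)
  list(statistic = obs, p = p)
}

signed_rank_normal <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  ties <- table(r)
  v <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  if (v <= 0) return(list(statistic = V, p = 1))
  z <- (V - mu) / sqrt(v)
  list(statistic = V, p = 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank test between two asymmetry samples
#'
#' Unpaired comparisons (e.g. patients vs controls) use the rank-sum
#' (Mann-Whitney) form; paired comparisons (e.g. static-AC ASYM vs each
#' kinetic-parameter ASYM within the same patients) use the signed-rank
#' form. Two-sided p-values come from exact enumeration of the permutation
#' distribution (midranks, so ties are handled) when the combined sample
#' size is at most `exact_limit`, and from the normal approximation with
#' tie correction otherwise. Degenerate samples (all observations tied,
#' or all paired differences zero) return p = 1 with `degenerate = TRUE`.
#'
#' @param a,b numeric samples (n >= 3 each; equal length when paired).
#' @param paired logical.
#' @param exact_limit combined-n threshold for exact enumeration.
#' @return list of class `group_comparison`: `test`, `method`,
#'   `statistic`, `p_value`, `mean_a`, `mean_b`, `degenerate`.
#' @export
compare_groups <- function(a, b, paired = FALSE, exact_limit = 12L) {
  if (length(a) < 3 || length(b) < 3)
    stop("domain error: need at least 3 observations per group")
  if (paired && length(a) != length(b))
    stop("domain error: paired samples must have equal length")
  if (paired) {
    d <- a - b
    degenerate <- all(d == 0)
    if (degenerate) {
      res <- list(statistic = 0, p = 1)
      method <- "degenerate"
    } else if (sum(d != 0) <= exact_limit) {
      res <- signed_rank_enumeration(d); method <- "exact enumeration"
    } else {
      res <- signed_rank_normal(d); method <- "normal approximation (tie-corrected)"
    }
    test <- "Wilcoxon signed-rank"
  } else {
    degenerate <- length(unique(c(a, b))) == 1L
    if (degenerate) {
      res <- list(statistic = length(a) * (length(a) + length(b) + 1) / 2, p = 1)
      method <- "degenerate"
    } else if (length(a) + length(b) <= exact_limit) {
      res <- rank_sum_enumeration(a, b); method <- "exact enumeration"
    } else {
      res <- rank_sum_normal(a, b); method <- "normal approximation (tie-corrected)"
    }
    test <- "Wilcoxon rank-sum"
  }
  structure(list(test = test, method = method, statistic = res$statistic,
                 p_value = res$p, mean_a = mean(a), mean_b = mean(b),
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %g, p = %.4g (means %.4g vs %.4g)%s\n",
              x$test, x$method, x$statistic, x$p_value, x$mean_a, x$mean_b,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Spearman correlation matrix of per-subject asymmetry indices
#'
#' Rank correlation (midranks under ties) between the asymmetry indices of
#' each pair of parameters across subjects, with two-sided p-values from
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom (approximate at small n). A constant column has no defined rank
#' correlation and is reported as NA.
#'
#' @param table data.frame or matrix of per-subject values, one numeric
#'   column per parameter (>= 5 complete rows).
#' @return list of class `correlation_matrix`: `rho` and `p` (symmetric
#'   matrices with unit / NA diagonal), `n`.
#' @export
correlate_asym <- function(table) {
  m <- as.matrix(as.data.frame(table)[, vapply(as.data.frame(table),
                                               is.numeric, logical(1))])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 5) stop("domain error: need at least 5 complete subjects")
  p <- ncol(m)
  ranks <- apply(m, 2, rank)
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  pv <- rho
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (stats::sd(ranks[, i]) == 0 || stats::sd(ranks[, j]) == 0) next
      if (i == j) { rho[i, j] <- 1; pv[i, j] <- NA_real_; next }
      r <- stats::cor(ranks[, i], ranks[, j])
      rho[i, j] <- r
      if (abs(r) >= 1) { pv[i, j] <- 0; next }
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      pv[i, j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(rho = rho, p = pv, n = n), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Spearman rank correlations (n = %d subjects):\n", x$n))
  print(round(x$rho, 3))
  invisible(x)
}
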