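test_that("asymmetry index matches its formula and symmetries", {
  expect_equal(asym_index(1.25, 0.75), 0.5)
  expect_equal(asym_index(3, 3), 0)
  expect_equal(asym_index(7e-4, 7e-4), 0)
  expect_error(asym_index(1, -1), "undefined-index")

  set.seed(21)
  c0 <- runif(50, 0.01, 5); i0 <- runif(50, 0.01, 5)
  # antisymmetry under side swap
  expect_equal(asym_index(c0, i0), -asym_index(i0, c0))
  # scale invariance (why an uncalibrated input function is admissible)
  for (a in c(1e-3, 0.37, 12, 1e4))
    expect_equal(asym_index(a * c0, a * i0), asym_index(c0, i0),
                 tolerance = 1e-12)
  # bounded for nonnegative inputs
  expect_true(all(abs(asym_index(c0, i0)) <= 2))
})

test_that("control averaging pools |ASYM| over the evaluation regions", {
  regs <- paste0("r", 1:6)
  rec <- data.frame(subject_id = "C01", region_id = regs, parameter = "K1",
                    asym = c(0.01, -0.02, 0.03, 0.00, 0.02, -0.04))
  out <- control_mean_abs_asym(rec, regs)
  expect_equal(unname(out["K1"]), 0.02)

  # sign flips change nothing
  rec2 <- rec; rec2$asym <- -rec2$asym
  expect_equal(control_mean_abs_asym(rec2, regs), out)

  sym <- rec; sym$asym <- 0
  expect_equal(unname(control_mean_abs_asym(sym, regs)["K1"]), 0)

  expect_error(control_mean_abs_asym(rec[-1, ], regs), "incomplete-subject")
})

test_that("rank-sum p-values equal exact enumeration at small n", {
  # fully separated 5 vs 5: two-sided p = 2/252
  a <- 1:5; b <- 11:15
  cmp <- compare_groups(a, b)
  expect_equal(cmp$p_value, 2 / 252)
  expect_match(cmp$method, "exact")

  set.seed(31)
  for (rep in 1:12) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 1)   # rounding induces occasional ties
    y <- round(rnorm(n2, 0.5), 1)
    got <- compare_groups(x, y)
    expect_equal(got$p_value, oracle_ranksum_p(x, y))
    # cross-check against the reference implementation when tie-free
    if (!anyDuplicated(c(x, y))) {
      ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
      expect_equal(got$p_value, ref$p.value)
    }
  }
})

test_that("signed-rank p-values equal exact enumeration at small n", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n, 0.3), 1)
    got <- compare_groups(x, y, paired = TRUE)
    expect_equal(got$p_value, oracle_signedrank_p(x - y))
    d <- x - y
    if (!anyDuplicated(abs(d[d != 0])) && all(d != 0)) {
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                                correct = FALSE)
      expect_equal(got$p_value, ref$p.value)
    }
  }
})

test_that("degenerate and large-sample branches behave as documented", {
  x <- c(1, 2, 3, 4, 5)
  cmp <- compare_groups(x, x, paired = TRUE)
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_value, 1)

  cmp2 <- compare_groups(rep(2, 4), rep(2, 5))
  expect_true(cmp2$degenerate)
  expect_equal(cmp2$p_value, 1)

  # above the enumeration limit the tie-corrected normal approximation is
  # used and agrees with the reference implementation (no continuity corr.)
  set.seed(51)
  a <- rnorm(10); b <- rnorm(12, 0.8)
  got <- compare_groups(a, b)
  expect_match(got$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)

  expect_error(compare_groups(1:2, 1:5), "at least 3")
  expect_error(compare_groups(1:4, 1:5, paired = TRUE), "equal length")
})

test_that("Spearman matrix: monotone data, ties, symmetry, invariance", {
  x <- c(1, 2, 3, 5, 8, 13)
  tab <- data.frame(a = x, b = exp(x), c = -x^3)
  cm <- correlate_asym(tab)
  expect_equal(cm$rho["a", "b"], 1)
  expect_equal(cm$rho["a", "c"], -1)
  expect_equal(cm$p["a", "b"], 0)
  expect_equal(cm$rho, t(cm$rho))
  expect_true(all(diag(cm$rho) == 1))

  # tied case, n = 6: oracle from explicitly constructed midranks
  u <- c(1, 2, 2, 3, 4, 4)
  v <- c(5, 5, 7, 8, 8, 9)
  ru <- c(1, 2.5, 2.5, 4, 5.5, 5.5)   # midranks by hand
  rv <- c(1.5, 1.5, 3, 4.5, 4.5, 6)
  rho_hand <- sum((ru - mean(ru)) * (rv - mean(rv))) /
    sqrt(sum((ru - mean(ru))^2) * sum((rv - mean(rv))^2))
  cm2 <- correlate_asym(data.frame(u = u, v = v))
  expect_equal(cm2$rho["u", "v"], rho_hand)
  expect_equal(cm2$rho["u", "v"],
               stats::cor(u, v, method = "spearman"))

  # monotone-transform invariance of rho
  set.seed(61)
  w <- rnorm(8); z <- rnorm(8)
  r1 <- correlate_asym(data.frame(w = w, z = z))$rho["w", "z"]
  r2 <- correlate_asym(data.frame(w = exp(w), z = z^3))$rho["w", "z"]
  expect_equal(r1, r2)

  # constant column: undefined, reported missing
  cm3 <- correlate_asym(data.frame(a = 1:6, b = rep(2, 6)))
  expect_true(is.na(cm3$rho["a", "b"]))
  expect_error(correlate_asym(data.frame(a = 1:4, b = 4:1)), "at least 5")
})
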