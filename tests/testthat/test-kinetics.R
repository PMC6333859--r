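test_that("Ki follows the macro-parameter formula with its degenerate limits", {
  expect_equal(compute_ki(0.10, 0.15, 0.05), 0.025)
  expect_equal(compute_ki(0.10, 0.15, 0), 0)      # no trapping
  expect_equal(compute_ki(0.10, 0, 0.05), 0.10)   # no efflux: Ki = K1
  expect_equal(compute_ki(0.3, 0, 0), 0)          # k2 + k3 == 0 limit
  expect_error(compute_ki(-0.1, 0.1, 0.1), "domain error")
})

test_that("parameter and input containers enforce their invariants", {
  expect_error(twotcm_params(0.1, 0.1, 0.1, vB = 1), "domain error")
  expect_error(twotcm_params(-0.1, 0.1, 0.1), "domain error")
  p <- twotcm_params(0.102, 0.13, 0.062)
  expect_equal(p$Ki, compute_ki(0.102, 0.13, 0.062))

  expect_error(plasma_input(c(1, 1), c(2, 2)), "strictly increasing")
  expect_error(plasma_input(c(0, 1), c(2, -1)), "nonnegative")
  inp <- plasma_input(c(1, 2, 3), c(0, 10, 5))
  expect_equal(eval_plasma(inp, c(0.5, 1.5, 2.5)), c(0, 5, 7.5))
  expect_error(eval_plasma(inp, 4), "does not cover")
})

test_that("zero-influx and constant-input closed forms hold", {
  p0 <- twotcm_params(0, 0.1, 0.05)
  tac0 <- forward_2tcm(p0, the_input, the_schedule)
  expect_equal(tac0$values, rep(0, the_schedule$n))

  # vB-only tissue is the frame-averaged input
  pv <- twotcm_params(0, 0.1, 0.05, vB = 0.1)
  tacv <- forward_2tcm(pv, the_input, the_schedule)
  cp_avg <- frame_average(function(t) eval_plasma(the_input, t / 60),
                          the_schedule)
  expect_equal(tacv$values, 0.1 * cp_avg, tolerance = 1e-7)

  # constant Cp = C0 from t = 0: symbolic solution of the ODE system
  C0 <- 50
  const_inp <- plasma_input(c(0, 120), c(C0, C0))
  K1 <- 0.09; k2 <- 0.12; k3 <- 0.05; b <- k2 + k3
  p <- twotcm_params(K1, k2, k3)
  tt <- c(1, 5, 30)
  got <- forward_2tcm_curve(p, const_inp, tt)
  C1 <- K1 * C0 * (1 - exp(-b * tt)) / b
  C2 <- (K1 * k3 * C0 / b) * (tt - (1 - exp(-b * tt)) / b)
  expect_equal(got, C1 + C2, tolerance = 1e-12)
})

test_that("forward model agrees with an independent stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  p <- twotcm_params(0.102, 0.13, 0.062, vB = 0.05)
  cp <- function(t) stats::approx(the_input$times_min, the_input$conc,
                                  xout = t, yleft = 0, rule = 2)$y
  rhs <- function(t, y, parms) {
    list(c(parms[1] * cp(t) - (parms[2] + parms[3]) * y[1],
           parms[3] * y[1],
           y[1] + y[2]))  # running integral of the tissue signal
  }
  bounds <- sort(unique(c(0, s_to_min(the_schedule$starts),
                          s_to_min(the_schedule$ends))))
  sol <- deSolve::ode(c(0, 0, 0), bounds, rhs, c(0.102, 0.13, 0.062),
                      method = "lsoda", rtol = 1e-11, atol = 1e-13)
  i1 <- match(s_to_min(the_schedule$starts), bounds)
  i2 <- match(s_to_min(the_schedule$ends), bounds)
  dur <- s_to_min(the_schedule$durations)
  tis_avg <- (sol[i2, 4] - sol[i1, 4]) / dur
  cp_avg <- frame_average(function(t) cp(t / 60), the_schedule)
  oracle <- (1 - 0.05) * tis_avg + 0.05 * cp_avg
  mine <- forward_2tcm(p, the_input, the_schedule)$values
  expect_lt(max(abs(mine - oracle) / pmax(oracle, 1e-9)), 1e-5)
})

test_that("forward model is homogeneous in the input and monotone in k3", {
  p <- twotcm_params(0.1, 0.15, 0.05)
  base <- forward_2tcm(p, the_input, the_schedule)$values
  scaled_inp <- plasma_input(the_input$times_min, 3.7 * the_input$conc)
  expect_equal(forward_2tcm(p, scaled_inp, the_schedule)$values, 3.7 * base,
               tolerance = 1e-12)

  late <- which(the_schedule$starts >= 2400)
  prev <- forward_2tcm(twotcm_params(0.1, 0.15, 0.01), the_input,
                       the_schedule)$values
  for (k3 in c(0.03, 0.06, 0.12, 0.3)) {
    cur <- forward_2tcm(twotcm_params(0.1, 0.15, k3), the_input,
                        the_schedule)$values
    expect_true(all(cur[late] >= prev[late] - 1e-10))
    prev <- cur
  }
})

test_that("late-time slope on a constant infusion approaches Ki (Patlak limit)", {
  C0 <- 10
  const_inp <- plasma_input(c(0, 200), c(C0, C0))
  for (pars in list(c(0.1, 0.15, 0.05), c(0.08, 0.3, 0.12))) {
    p <- twotcm_params(pars[1], pars[2], pars[3])
    t0 <- 5 / (pars[2] + pars[3])
    tt <- c(t0 + 5, t0 + 25)
    ct <- forward_2tcm_curve(p, const_inp, tt)
    slope <- diff(ct) / diff(tt) / C0
    expect_equal(slope, p$Ki, tolerance = 0.02)
  }
})

test_that("noiseless fits recover the generating parameters", {
  truth <- twotcm_params(0.102, 0.13, 0.062)
  tac <- forward_2tcm(truth, the_input, the_schedule)
  fit <- fit_2tcm(tac, the_input, fit_config())
  expect_true(fit$converged)
  expect_equal(fit$params$K1, truth$K1, tolerance = 1e-3)
  expect_equal(fit$params$k2, truth$k2, tolerance = 1e-3)
  expect_equal(fit$params$k3, truth$k3, tolerance = 1e-3)
  expect_lt(abs(fit$params$K1 / truth$K1 - 1), 0.001)
  expect_lt(abs(fit$params$k2 / truth$k2 - 1), 0.001)
  expect_lt(abs(fit$params$k3 / truth$k3 - 1), 0.001)
})

test_that("noiseless fits recover a seeded grid of truth vectors within 0.5%", {
  set.seed(2024)
  grid <- data.frame(K1 = runif(20, 0.03, 0.5),
                     k2 = runif(20, 0.03, 0.9),
                     k3 = runif(20, 0.01, 0.4))
  cfg <- fit_config(restarts = 5)
  for (i in seq_len(nrow(grid))) {
    truth <- twotcm_params(grid$K1[i], grid$k2[i], grid$k3[i])
    tac <- forward_2tcm(truth, the_input, the_schedule)
    fit <- fit_2tcm(tac, the_input, cfg)
    expect_lt(abs(fit$params$K1 / truth$K1 - 1), 0.005)
    expect_lt(abs(fit$params$k2 / truth$k2 - 1), 0.005)
    expect_lt(abs(fit$params$k3 / truth$k3 - 1), 0.005)
  }
})

test_that("degenerate and invalid fit inputs are handled explicitly", {
  zero <- tissue_tac(the_schedule, rep(0, the_schedule$n))
  expect_warning(fit <- fit_2tcm(zero, the_input), "all-zero TAC")
  expect_true(fit$degenerate)
  expect_equal(fit$params$K1, 0)

  short <- make_frame_schedule(list(c(4, 60)))
  stac <- tissue_tac(short, rep(1, 4))
  expect_error(fit_2tcm(stac, the_input), "at least 8 frames")
})

test_that("fits are deterministic given the config seed", {
  truth <- twotcm_params(0.1, 0.2, 0.07)
  clean <- forward_2tcm(truth, the_input, the_schedule)$values
  set.seed(5)
  tac <- tissue_tac(the_schedule, clean + rnorm(length(clean), 0, 0.02 * clean))
  f1 <- fit_2tcm(tac, the_input, fit_config(seed = 9))
  f2 <- fit_2tcm(tac, the_input, fit_config(seed = 9))
  expect_identical(f1$params, f2$params)
})

test_that("the macro-parameter Ki is better identified than k3 under noise", {
  truth <- twotcm_params(0.10, 0.14, 0.06)
  clean <- forward_2tcm(truth, the_input, the_schedule)$values
  cfg <- fit_config(restarts = 2, seed = 3)
  set.seed(20240601)
  rel <- t(replicate(50, {
    y <- clean + rnorm(length(clean), 0, 0.03 * clean)
    f <- fit_2tcm(tissue_tac(the_schedule, y), the_input, cfg)
    c(ki = abs(f$params$Ki / truth$Ki - 1),
      k3 = abs(f$params$k3 / truth$k3 - 1))
  }))
  med <- apply(rel, 2, stats::median)
  expect_lt(med[["ki"]], med[["k3"]])
  # realized medians frozen as regression fixtures (same seed, same path)
  expect_equal(unname(med), c(0.0142729661, 0.0552826301), tolerance = 1e-3)
})
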