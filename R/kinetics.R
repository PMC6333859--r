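#' Net metabolic flux Ki from 2TCM micro-parameters
#'
#' For the irreversible two-tissue compartment model the net influx
#' (metabolic flux) macro-parameter is `Ki = K1 * k3 / (k2 + k3)`,
#' the model-based analogue of the Patlak slope. When `k2 + k3 == 0`
#' (no exchange at all) Ki is defined as 0, the continuous limit.
#'
#' @param K1 influx rate constant, mL min^-1 mL^-1.
#' @param k2 efflux rate constant, min^-1.
#' @param k3 phosphorylation (trapping) rate constant, min^-1.
#' @return Ki, mL min^-1 mL^-1. Vectorized over its arguments.
#' @examples
#' compute_ki(0.10, 0.15, 0.05)  # 0.025
#' @export
compute_ki <- function(K1, k2, k3) {
  n <- max(length(K1), length(k2), length(k3))
  K1 <- rep_len(K1, n); k2 <- rep_len(k2, n); k3 <- rep_len(k3, n)
  if (any(K1 < 0) || any(k2 < 0) || any(k3 < 0))
    stop("domain error: rate constants must be nonnegative")
  denom <- k2 + k3
  ifelse(denom > 0, K1 * k3 / denom, 0)
}

#' Parameters of the irreversible two-tissue compartment model
#'
#' @param K1 influx rate constant, mL min^-1 mL^-1, in [0, Inf).
#' @param k2 efflux rate constant, min^-1.
#' @param k3 phosphorylation rate constant, min^-1 (k4 = 0 throughout:
#'   phosphorylated tracer is trapped).
#' @param vB blood-volume fraction, unitless in [0, 1); default 0.
#' @return An object of class `twotcm_params` with fields `K1`, `k2`,
#'   `k3`, `vB` and the derived `Ki` (see [compute_ki()]).
#' @export
twotcm_params <- function(K1, k2, k3, vB = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, vB = vB)
  if (any(!is.finite(vals))) stop("domain error: non-finite parameter")
  if (K1 < 0 || k2 < 0 || k3 < 0)
    stop("domain error: rate constants must be nonnegative")
  if (vB < 0 || vB >= 1)
    stop("domain error: vB must lie in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, vB = vB,
                 Ki = compute_ki(K1, k2, k3)),
            class = "twotcm_params")
}

#' @export
print.twotcm_params <- function(x, ...) {
  cat(sprintf("2TCM params: K1=%.4g mL/min/mL, k2=%.4g /min, k3=%.4g /min, vB=%.3g; Ki=%.4g\n",
              x$K1, x$k2, x$k3, x$vB, x$Ki))
  invisible(x)
}

#' Plasma (input-function) curve
#'
#' A metabolite-free arterial plasma concentration curve, represented by
#' samples and interpolated piecewise-linearly; the curve is defined to
#' be 0 before the first sample (pre-bolus baseline).
#'
#' @param times_min sample times, minutes, strictly increasing.
#' @param conc concentrations, kBq mL^-1, nonnegative.
#' @return An object of class `plasma_input`.
#' @export
plasma_input <- function(times_min, conc) {
  times_min <- as.numeric(times_min); conc <- as.numeric(conc)
  if (length(times_min) < 2L) stop("domain error: need at least 2 samples")
  if (length(times_min) != length(conc))
    stop("domain error: times and concentrations differ in length")
  if (is.unsorted(times_min, strictly = TRUE))
    stop("domain error: sample times must be strictly increasing")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("domain error: concentrations must be finite and nonnegative")
  structure(list(times_min = times_min, conc = conc), class = "plasma_input")
}

#' Evaluate a plasma input curve
#'
#' Piecewise-linear interpolation; 0 before the first sample. Times past
#' the last sample are a domain error (the input must cover the request).
#'
#' @param input a [plasma_input()].
#' @param t_min times to evaluate, minutes.
#' @return concentrations at `t_min`.
#' @export
eval_plasma <- function(input, t_min) {
  stopifnot(inherits(input, "plasma_input"))
  if (any(t_min > max(input$times_min) + 1e-9))
    stop("domain error: input function does not cover the requested times")
  stats::approx(input$times_min, input$conc, xout = t_min,
                yleft = 0, rule = 2)$y
}

#' @export
print.plasma_input <- function(x, ...) {
  cat(sprintf("plasma_input: %d samples over %.2f-%.2f min, peak %.4g kBq/mL\n",
              length(x$times_min), min(x$times_min), max(x$times_min),
              max(x$conc)))
  invisible(x)
}

#' Tissue time-activity curve for one VOI
#'
#' @param schedule a [frame_schedule()].
#' @param values per-frame activity concentration, kBq mL^-1.
#' @param voi_id region identifier.
#' @param side one of "ipsilateral", "contralateral", "left", "right".
#' @return An object of class `tissue_tac`.
#' @export
tissue_tac <- function(schedule, values, voi_id = NA_character_,
                       side = NA_character_) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != schedule$n)
    stop("domain error: one value per frame required")
  if (any(!is.finite(values)))
    stop("domain error: TAC values must be finite")
  structure(list(schedule = schedule, values = values,
                 voi_id = voi_id, side = side), class = "tissue_tac")
}

#' @export
print.tissue_tac <- function(x, ...) {
  cat(sprintf("tissue_tac: voi=%s side=%s, %d frames, max %.4g kBq/mL\n",
              x$voi_id, x$side, x$schedule$n, max(x$values)))
  invisible(x)
}

## ---- exact 2TCM propagation for piecewise-linear input -------------------
##
## State (C1, C2): dC1/dt = K1*Cp - beta*C1, dC2/dt = k3*C1, beta = k2+k3.
## Over a segment where Cp(t0+s) = a + b*s the update and the segment
## integrals of C1, C2 are closed-form in the phi functions
##   phi_k(x) = (e^{-x} - sum_{j<k} (-x)^j/j!) / (-x)^k,
## i.e. phi1=(1-e^-x)/x, phi2=(x-1+e^-x)/x^2, ... evaluated by series for
## small x to avoid cancellation. This makes the forward model exact (to
## float) for the declared piecewise-linear input contract.

phi_funs <- function(x) {
  phi1 <- ifelse(x > 1e-2, -expm1(-x) / pmax(x, .Machine$double.xmin),
                 1 - x/2 + x^2/6 - x^3/24 + x^4/120 - x^5/720)
  phi2 <- ifelse(x > 1e-2, (x - 1 + exp(-x)) / pmax(x, .Machine$double.xmin)^2,
                 1/2 - x/6 + x^2/24 - x^3/120 + x^4/720 - x^5/5040)
  phi3 <- ifelse(x > 5e-2, (x^2/2 - x + 1 - exp(-x)) / pmax(x, .Machine$double.xmin)^3,
                 1/6 - x/24 + x^2/120 - x^3/720 + x^4/5040 - x^5/40320)
  phi4 <- ifelse(x > 5e-2, (x^3/6 - x^2/2 + x - 1 + exp(-x)) / pmax(x, .Machine$double.xmin)^4,
                 1/24 - x/120 + x^2/720 - x^3/5040 + x^4/40320 - x^5/362880)
  list(phi1 = phi1, phi2 = phi2, phi3 = phi3, phi4 = phi4)
}

# Segment decomposition of an input curve over [0, t_end]: returns knots
# (minutes) and per-segment linear coefficients (a = value at left end,
# b = slope), honouring the zero-before-first-sample convention.
input_segments <- function(input, knots_min) {
  knots <- sort(unique(c(0, knots_min, input$times_min[
    input$times_min > 0 & input$times_min < max(knots_min)])))
  h <- diff(knots)
  left <- knots[-length(knots)]
  right <- knots[-1]
  t1 <- input$times_min[1]
  aL <- eval_plasma(input, left)
  aR <- eval_plasma(input, right)
  # segments that end at or before the first sample are pre-bolus zero
  pre <- right <= t1 + 1e-12
  aL[pre] <- 0; aR[pre] <- 0
  list(knots = knots, h = h, a = aL, b = (aR - aL) / h)
}

# Core propagator: instantaneous C1, C2 and cumulative integrals at knots.
twotcm_propagate <- function(K1, k2, k3, seg) {
  beta <- k2 + k3
  h <- seg$h; a <- seg$a; b <- seg$b
  x <- beta * h
  ph <- phi_funs(x)
  E <- exp(-x)
  n <- length(h)
  C1 <- numeric(n + 1); C2 <- numeric(n + 1)
  iC1 <- numeric(n + 1); iC2 <- numeric(n + 1)
  # vectorized per-segment pieces that do not depend on the state
  dC1 <- K1 * h * (a * ph$phi1 + b * h * ph$phi2)
  g1 <- K1 * h^2 * (a * ph$phi2 + b * h * ph$phi3)
  g2 <- K1 * h^3 * (a * ph$phi3 + b * h * ph$phi4)
  hph1 <- h * ph$phi1
  hph2 <- h^2 * ph$phi2
  for (i in seq_len(n)) {
    c1 <- C1[i]; c2 <- C2[i]
    int1 <- c1 * hph1[i] + g1[i]
    int2 <- c2 * h[i] + k3 * (c1 * hph2[i] + g2[i])
    C1[i + 1] <- c1 * E[i] + dC1[i]
    C2[i + 1] <- c2 + k3 * int1
    iC1[i + 1] <- iC1[i] + int1
    iC2[i + 1] <- iC2[i] + int2
  }
  list(knots = seg$knots, C1 = C1, C2 = C2, iC1 = iC1, iC2 = iC2)
}

# Frame-averaging machinery shared by forward_2tcm and fit_2tcm: all the
# parameter-independent geometry is precomputed once.
make_2tcm_predictor <- function(input, schedule) {
  stopifnot(inherits(input, "plasma_input"), inherits(schedule, "frame_schedule"))
  ends_min <- s_to_min(max(schedule$ends))
  if (max(input$times_min) < ends_min - 1e-9)
    stop("domain error: input function does not cover the frame schedule")
  fr_start <- s_to_min(schedule$starts)
  fr_end <- s_to_min(schedule$ends)
  seg <- input_segments(input, c(fr_start, fr_end))
  i_start <- match_knot(seg$knots, fr_start)
  i_end <- match_knot(seg$knots, fr_end)
  dur_min <- fr_end - fr_start
  # exact cumulative integral of the piecewise-linear Cp itself (vB term)
  iCp <- c(0, cumsum(seg$h * (seg$a + seg$b * seg$h / 2)))
  cp_frame <- (iCp[i_end] - iCp[i_start]) / dur_min
  function(K1, k2, k3, vB = 0) {
    pr <- twotcm_propagate(K1, k2, k3, seg)
    iCt <- pr$iC1 + pr$iC2
    tis <- (iCt[i_end] - iCt[i_start]) / dur_min
    (1 - vB) * tis + vB * cp_frame
  }
}

match_knot <- function(knots, t) {
  idx <- vapply(t, function(ti) which.min(abs(knots - ti)), integer(1))
  if (any(abs(knots[idx] - t) > 1e-9))
    stop("internal error: frame boundary missing from knot grid")
  idx
}

#' Forward-simulate the irreversible 2TCM
#'
#' Solves dC1/dt = K1*Cp - (k2+k3)*C1, dC2/dt = k3*C1 (C1(0)=C2(0)=0)
#' against a piecewise-linear plasma input and returns the frame-averaged
#' model concentration `Cmodel = (1-vB)*(C1+C2) + vB*Cp`. The state is
#' propagated by the closed-form solution on each linear input segment
#' (segment grid = union of input sample times and frame boundaries), so
#' both the instantaneous solution and the frame averages are exact to
#' floating point for the declared input interpolation.
#'
#' @param params a [twotcm_params()].
#' @param input a [plasma_input()] covering the schedule.
#' @param schedule a [frame_schedule()].
#' @param voi_id,side metadata carried into the returned [tissue_tac()].
#' @return A [tissue_tac()] of frame-averaged model concentrations.
#' @export
forward_2tcm <- function(params, input, schedule,
                         voi_id = NA_character_, side = NA_character_) {
  stopifnot(inherits(params, "twotcm_params"))
  pred <- make_2tcm_predictor(input, schedule)
  tissue_tac(schedule, pred(params$K1, params$k2, params$k3, params$vB),
             voi_id = voi_id, side = side)
}

#' Instantaneous 2TCM model curve
#'
#' Same model as [forward_2tcm()] but returning the instantaneous (not
#' frame-averaged) concentration at arbitrary times.
#'
#' @inheritParams forward_2tcm
#' @param t_min times, minutes, within the input support.
#' @return numeric vector of model concentrations at `t_min`.
#' @export
forward_2tcm_curve <- function(params, input, t_min) {
  stopifnot(inherits(params, "twotcm_params"))
  if (any(t_min < 0)) stop("domain error: negative times")
  seg <- input_segments(input, sort(unique(c(t_min, max(t_min)))))
  pr <- twotcm_propagate(params$K1, params$k2, params$k3, seg)
  idx <- match_knot(seg$knots, t_min)
  ct <- (1 - params$vB) * (pr$C1[idx] + pr$C2[idx]) +
    params$vB * eval_plasma(input, t_min)
  ct
}

#' Fit settings for [fit_2tcm()]
#'
#' @param lower,upper named bounds on `K1` (mL min^-1 mL^-1), `k2`, `k3`
#'   (min^-1) and `vB` (fraction). Defaults span physiological FDG brain
#'   ranges: K1 in [0,1], k2 in [0,2], k3 in [0,1], vB in [0,0.2].
#' @param weights frame weighting: `"duration"` (w_f proportional to frame
#'   duration, a uniform-variance-rate approximation; default),
#'   `"duration_sq_over_value"`, or `"uniform"`.
#' @param restarts number of multi-start initial points (>= 1); the first
#'   start is a fixed physiological midpoint, the rest are drawn uniformly
#'   inside the bounds from a generator seeded by `seed`.
#' @param fit_vB logical; free the blood-volume fraction? Default FALSE
#'   (vB fixed at `vB_fixed`), matching the plain two-tissue model
#'   statement without a blood term.
#' @param vB_fixed value of vB when not fitted.
#' @param seed integer seed for the multi-start draws (fits are
#'   deterministic given the config).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = c(K1 = 0, k2 = 0, k3 = 0, vB = 0),
                       upper = c(K1 = 1, k2 = 2, k3 = 1, vB = 0.2),
                       weights = c("duration", "duration_sq_over_value", "uniform"),
                       restarts = 5L, fit_vB = FALSE, vB_fixed = 0,
                       seed = 1L) {
  weights <- match.arg(weights)
  stopifnot(restarts >= 1, all(lower <= upper))
  structure(list(lower = lower, upper = upper, weights = weights,
                 restarts = as.integer(restarts), fit_vB = fit_vB,
                 vB_fixed = vB_fixed, seed = as.integer(seed)),
            class = "fit_config")
}

frame_weights <- function(tac, type) {
  dur <- s_to_min(tac$schedule$durations)
  w <- switch(type,
              duration = dur,
              duration_sq_over_value = dur^2 / pmax(abs(tac$values), 1e-6),
              uniform = rep(1, tac$schedule$n))
  w / mean(w)
}

#' Fit the irreversible 2TCM to a tissue TAC
#'
#' Bounded weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) with seeded multi-starts. Minimizes
#' `sum_f w_f (TAC_f - model_f)^2` over (K1, k2, k3) and optionally vB;
#' Ki is derived from the estimate. Deterministic given the config.
#'
#' @param tac a [tissue_tac()] (>= 8 frames).
#' @param input a [plasma_input()] covering the schedule.
#' @param config a [fit_config()].
#' @return A list of class `twotcm_fit`: `params` ([twotcm_params()]),
#'   `wrss`, `se` (per-parameter standard errors from the curvature at
#'   the optimum; NA when not identifiable), `converged`, `restarts_used`,
#'   `degenerate` (TRUE for an all-zero TAC, reported at the boundary).
#' @export
fit_2tcm <- function(tac, input, config = fit_config()) {
  stopifnot(inherits(tac, "tissue_tac"), inherits(config, "fit_config"))
  if (tac$schedule$n < 8L)
    stop("domain error: at least 8 frames required for a 2TCM fit")
  pred <- make_2tcm_predictor(input, tac$schedule)
  w <- frame_weights(tac, config$weights)
  sw <- sqrt(w)
  pnames <- c("K1", "k2", "k3", if (config$fit_vB) "vB")
  lo <- config$lower[pnames]; hi <- config$upper[pnames]

  model_of <- function(p) {
    vB <- if (config$fit_vB) p[["vB"]] else config$vB_fixed
    pred(p[["K1"]], p[["k2"]], p[["k3"]], vB)
  }
  resid_of <- function(p) sw * (tac$values - model_of(p))

  if (all(tac$values == 0)) {
    params <- twotcm_params(0, 0, 0, if (config$fit_vB) 0 else config$vB_fixed)
    warning("all-zero TAC: boundary estimate returned")
    return(structure(list(params = params, wrss = 0,
                          se = stats::setNames(rep(NA_real_, length(pnames)), pnames),
                          converged = TRUE, restarts_used = 0L,
                          degenerate = TRUE),
                     class = "twotcm_fit"))
  }

  starts <- multi_starts(lo, hi, config$restarts, config$seed)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = lo, upper = hi,
                         fn = resid_of,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(params = NULL, wrss = NA_real_,
                          se = stats::setNames(rep(NA_real_, length(pnames)), pnames),
                          converged = FALSE, restarts_used = config$restarts,
                          degenerate = FALSE),
                     class = "twotcm_fit"))
  est <- stats::setNames(pmin(pmax(unlist(best$par), lo), hi), pnames)
  vB <- if (config$fit_vB) est[["vB"]] else config$vB_fixed
  params <- twotcm_params(est[["K1"]], est[["k2"]], est[["k3"]], vB)
  wrss <- best$deviance
  se <- fit_se(resid_of, est, lo, hi, wrss, tac$schedule$n)
  structure(list(params = params, wrss = wrss, se = se,
                 converged = best$info %in% 1:4,
                 restarts_used = config$restarts, degenerate = FALSE),
            class = "twotcm_fit")
}

multi_starts <- function(lo, hi, restarts, seed) {
  default <- pmin(pmax(c(K1 = 0.1, k2 = 0.15, k3 = 0.05, vB = 0.03)[names(lo)],
                       lo + 0.05 * (hi - lo)), hi - 0.05 * (hi - lo))
  extra <- max(0L, restarts - 1L)
  rand <- if (extra > 0) {
    with_local_seed(seed, {
      matrix(stats::runif(extra * length(lo),
                          lo + 0.02 * (hi - lo), hi - 0.02 * (hi - lo)),
             nrow = extra, byrow = TRUE)
    })
  } else NULL
  m <- rbind(default, rand)
  colnames(m) <- names(lo)
  rownames(m) <- NULL
  m
}

# run expr under a private RNG state, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

fit_se <- function(resid_of, est, lo, hi, wrss, nframes) {
  p <- length(est)
  J <- matrix(NA_real_, nframes, p)
  r0 <- resid_of(est)
  for (j in seq_len(p)) {
    dj <- max(1e-6, 1e-6 * abs(est[j]))
    ep <- est; ep[j] <- min(est[j] + dj, hi[j])
    em <- est; em[j] <- max(est[j] - dj, lo[j])
    denom <- ep[j] - em[j]
    if (denom <= 0) next
    J[, j] <- (resid_of(ep) - resid_of(em)) / denom
  }
  sig2 <- wrss / max(1, nframes - p)
  se <- rep(NA_real_, p)
  ok <- colSums(is.na(J)) == 0
  if (all(ok)) {
    cv <- tryCatch(solve(crossprod(J)) * sig2, error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)
      se[d >= 0] <- sqrt(d[d >= 0])
    }
  }
  stats::setNames(se, names(est))
}

#' @export
print.twotcm_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("2TCM fit: NOT CONVERGED\n")
  } else {
    cat(sprintf("2TCM fit: K1=%.4g k2=%.4g k3=%.4g vB=%.3g Ki=%.4g (WRSS %.4g, %s)\n",
                x$params$K1, x$params$k2, x$params$k3, x$params$vB,
                x$params$Ki, x$wrss,
                if (x$converged) "converged" else "not converged"))
  }
  invisible(x)
}
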