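#' Carotid ROI measurement
#'
#' A measured carotid-ROI activity curve together with the curve of an
#' immediate background ROI on the same time base. Curves may be per-frame
#' or per-sample; only the shared time base matters.
#'
#' @param times_min sample (or frame mid) times, minutes.
#' @param cmeas measured carotid concentration, kBq mL^-1.
#' @param cbkgd background-ROI concentration, kBq mL^-1, same time base.
#' @return An object of class `carotid_measurement`.
#' @export
carotid_measurement <- function(times_min, cmeas, cbkgd) {
  times_min <- as.numeric(times_min)
  cmeas <- as.numeric(cmeas); cbkgd <- as.numeric(cbkgd)
  if (length(cmeas) != length(times_min) || length(cbkgd) != length(times_min))
    stop("domain error: carotid and background curves must share one time base")
  if (is.unsorted(times_min, strictly = TRUE))
    stop("domain error: times must be strictly increasing")
  if (any(!is.finite(cmeas)) || any(!is.finite(cbkgd)))
    stop("domain error: non-finite curve values")
  structure(list(times_min = times_min, cmeas = cmeas, cbkgd = cbkgd),
            class = "carotid_measurement")
}

#' Partial-volume coefficients for the carotid ROI
#'
#' @param rc recovery coefficient (fraction of true vessel signal measured
#'   inside the ROI), in (0, 1].
#' @param sp spill-in factor (background contamination fraction), in [0, 1).
#' @return An object of class `pvc_coefficients`.
#' @export
pvc_coefficients <- function(rc, sp) {
  if (!is.finite(rc) || rc <= 0 || rc > 1)
    stop("invalid-coefficients: RC must lie in (0, 1]")
  if (!is.finite(sp) || sp < 0 || sp >= 1)
    stop("invalid-coefficients: SP must lie in [0, 1)")
  structure(list(rc = rc, sp = sp), class = "pvc_coefficients")
}

#' Correct a carotid measurement into a plasma input function
#'
#' Inverts the partial-volume observation model
#' `Cmeas(t) = RC * Cinput(t) + SP * Cbkgd(t)`:
#' `Cinput(t) = (Cmeas(t) - SP * Cbkgd(t)) / RC`, pointwise. Negative
#' corrected samples (routine early-frame noise) are clipped to 0; the
#' number clipped is attached as attribute `n_clipped` and reported via
#' `message()` when nonzero. No blood scaling is applied anywhere: the
#' curve is used uncalibrated, which is admissible because the asymmetry
#' index is scale-invariant.
#'
#' @param meas a [carotid_measurement()].
#' @param coeff a [pvc_coefficients()].
#' @return A [plasma_input()] with attribute `n_clipped`.
#' @examples
#' m <- carotid_measurement(c(0.5, 1, 2), c(10, 10, 10), c(4, 4, 4))
#' correct_idif(m, pvc_coefficients(0.8, 0.2))  # (10 - 0.8)/0.8 = 11.5
#' @export
correct_idif <- function(meas, coeff) {
  stopifnot(inherits(meas, "carotid_measurement"),
            inherits(coeff, "pvc_coefficients"))
  raw <- (meas$cmeas - coeff$sp * meas$cbkgd) / coeff$rc
  n_clipped <- sum(raw < 0)
  if (n_clipped > 0)
    message(sprintf("correct_idif: clipped %d negative corrected sample(s) to 0",
                    n_clipped))
  out <- plasma_input(meas$times_min, pmax(raw, 0))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Mix a true input and background into a carotid measurement
#'
#' Forward direction of the partial-volume model, used by the simulator:
#' `Cmeas = RC * Ctrue + SP * Cbkgd`.
#'
#' @param ctrue true plasma curve: a [plasma_input()] or a numeric vector
#'   on `times_min`.
#' @param cbkgd background curve, numeric vector on the same time base.
#' @param coeff a [pvc_coefficients()].
#' @param times_min time base, minutes (required when `ctrue` is a
#'   [plasma_input()], ignored otherwise if `ctrue` is a vector and
#'   `times_min` given).
#' @return A [carotid_measurement()].
#' @export
mix_carotid <- function(ctrue, cbkgd, coeff, times_min = NULL) {
  stopifnot(inherits(coeff, "pvc_coefficients"))
  if (inherits(ctrue, "plasma_input")) {
    if (is.null(times_min)) times_min <- ctrue$times_min
    ctrue <- eval_plasma(ctrue, times_min)
  } else if (is.null(times_min)) {
    stop("domain error: times_min required when ctrue is a plain vector")
  }
  if (length(cbkgd) != length(ctrue))
    stop("domain error: curves must share one time base")
  carotid_measurement(times_min, coeff$rc * ctrue + coeff$sp * cbkgd, cbkgd)
}

#' Estimate RC and SP from the scanner point-spread function
#'
#' Simulates the partial-volume effect for a carotid-style ROI: an
#' infinite straight cylinder (the vessel) of the given diameter is
#' blurred by an isotropic Gaussian point-spread function with the
#' reconstructed image resolution (FWHM). Because the geometry is
#' translation-invariant along the vessel axis, the simulation is the 2D
#' cross-section on a fine grid. Two probes are used:
#' vessel intensity 1 in background 0 gives the recovery coefficient
#' `RC = mean blurred vessel-only signal inside the ROI`; vessel 0 in
#' background 1 gives the spill-in factor
#' `SP = mean blurred background-only signal inside the ROI`.
#'
#' @param fwhm_mm scanner resolution as Gaussian FWHM, mm (>= 0).
#' @param vessel_diameter_mm vessel diameter, mm (> 0); default 6 mm
#'   (adult common carotid).
#' @param roi_radius_mm radius of the circular ROI centred in the vessel,
#'   mm; default 2 mm (a ~2-voxel-wide core at typical PET voxel sizes).
#' @param grid_mm simulation grid pitch, mm (<= 0.5).
#' @param field_mm half-width of the simulated field, mm; must contain
#'   the ROI and vessel plus blur support.
#' @return A [pvc_coefficients()] with attribute `simulation` (a list with
#'   the settings used).
#' @examples
#' estimate_rc_sp(fwhm_mm = 0, vessel_diameter_mm = 6)  # RC = 1, SP = 0
#' @export
estimate_rc_sp <- function(fwhm_mm, vessel_diameter_mm = 6,
                           roi_radius_mm = 2, grid_mm = 0.5,
                           field_mm = NULL) {
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("geometry error: fwhm_mm must be >= 0")
  if (vessel_diameter_mm <= 0) stop("geometry error: vessel diameter must be > 0")
  if (grid_mm > 0.5) stop("geometry error: grid pitch must be <= 0.5 mm")
  if (roi_radius_mm > vessel_diameter_mm / 2)
    stop("geometry error: ROI larger than the vessel")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  if (is.null(field_mm))
    field_mm <- vessel_diameter_mm / 2 + max(6 * sigma, 10)
  x <- seq(-field_mm, field_mm, by = grid_mm)
  r2 <- outer(x^2, x^2, `+`)
  vessel <- (r2 <= (vessel_diameter_mm / 2)^2) * 1
  roi <- r2 <= roi_radius_mm^2
  if (!any(roi)) stop("geometry error: ROI contains no grid point")
  if (sigma == 0) {
    rc <- mean(vessel[roi]); sp <- mean((1 - vessel)[roi])
  } else {
    bl_v <- gaussian_blur2d(vessel, sigma / grid_mm)
    rc <- mean(bl_v[roi])
    sp <- mean((1 - bl_v)[roi])  # blur of (1 - vessel): blur is linear, blur(1)=1
  }
  out <- pvc_coefficients(min(rc, 1), max(sp, 0))
  attr(out, "simulation") <- list(fwhm_mm = fwhm_mm,
                                  vessel_diameter_mm = vessel_diameter_mm,
                                  roi_radius_mm = roi_radius_mm,
                                  grid_mm = grid_mm, field_mm = field_mm)
  out
}

# Separable 2D Gaussian blur by kernel-matrix multiplication; the kernel
# is truncated at 6 sigma and renormalized, so a constant image stays
# constant away from (and, by renormalization, at) the field edge.
gaussian_blur2d <- function(img, sigma_px) {
  n <- nrow(img)
  half <- ceiling(6 * sigma_px)
  offs <- (-half):half
  k <- exp(-offs^2 / (2 * sigma_px^2))
  K <- matrix(0, n, n)
  for (d in seq_along(offs)) {
    idx <- which(seq_len(n) + offs[d] >= 1 & seq_len(n) + offs[d] <= n)
    K[cbind(idx, idx + offs[d])] <- k[d]
  }
  K <- K / rowSums(K)
  K %*% img %*% t(K)
}

#' @export
print.pvc_coefficients <- function(x, ...) {
  cat(sprintf("PVC coefficients: RC = %.4f, SP = %.4f\n", x$rc, x$sp))
  invisible(x)
}
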