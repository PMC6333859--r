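#' Feng-type bolus plasma curve (closed form)
#'
#' Tri-exponential bolus shape standard in FDG simulation:
#' `A1*(t-tau)*exp(-l1*(t-tau)) + A2*exp(-l2*(t-tau)) + A3*exp(-l3*(t-tau))`
#' for `t >= tau`, 0 before the delay `tau`.
#'
#' @param t_min time, minutes.
#' @param A1,l1,A2,l2,A3,l3 amplitudes (kBq mL^-1; A1 per minute) and decay
#'   rates (min^-1).
#' @param delay_min bolus arrival delay tau, minutes.
#' @param scale overall multiplicative scale (injected-dose proxy).
#' @return concentrations at `t_min`.
#' @export
feng_curve <- function(t_min, A1 = 800, l1 = 4, A2 = 20, l2 = 0.01,
                       A3 = 20, l3 = 0.12, delay_min = 0.5, scale = 1) {
  s <- pmax(t_min - delay_min, 0)
  on <- as.numeric(t_min >= delay_min)
  scale * on * (A1 * s * exp(-l1 * s) + A2 * exp(-l2 * s) + A3 * exp(-l3 * s))
}

#' Simulate a bolus-injection plasma input function
#'
#' Samples a [feng_curve()] on a dense grid (1 s up to 3 min, 3 s to
#' 10 min, 15 s thereafter) and returns it as a [plasma_input()]. With a
#' seed, the amplitude is jittered log-normally (inter-subject dose /
#' delivery variability) and the delay uniformly by up to ±6 s.
#'
#' @param dose_proxy overall amplitude scale (arbitrary units; the
#'   downstream asymmetry analysis is scale-invariant).
#' @param duration_min last sample time, minutes; must cover the frame
#'   schedule to be used.
#' @param delay_min bolus arrival delay, minutes.
#' @param feng list of curve parameters overriding [feng_curve()] defaults
#'   (`A1`, `l1`, `A2`, `l2`, `A3`, `l3`).
#' @param seed optional integer; when given, amplitude and delay are
#'   jittered from a private seeded stream.
#' @param amplitude_jitter_sd sd of the log-normal amplitude jitter.
#' @return A [plasma_input()].
#' @export
simulate_input_function <- function(dose_proxy = 1, duration_min = 67.5,
                                    delay_min = 0.5, feng = list(),
                                    seed = NULL, amplitude_jitter_sd = 0.1) {
  if (dose_proxy <= 0) stop("spec error: dose proxy must be positive")
  if (delay_min < 0) stop("spec error: negative delay")
  scale <- dose_proxy
  if (!is.null(seed)) {
    jit <- with_local_seed(seed, list(a = stats::rnorm(1, 0, amplitude_jitter_sd),
                                      d = stats::runif(1, -0.1, 0.1)))
    scale <- scale * exp(jit$a)
    delay_min <- max(0, delay_min + jit$d)
  }
  t <- sort(unique(c(seq(0, 3, by = 1 / 60),
                     seq(3, 10, by = 0.05),
                     seq(10, duration_min, by = 0.25),
                     duration_min, delay_min)))
  args <- c(list(t_min = t, delay_min = delay_min, scale = scale), feng)
  conc <- do.call(feng_curve, args)
  if (any(conc < 0)) stop("spec error: input-function parameters produce negative values")
  if (t[which.max(conc)] > 2)
    stop("spec error: bolus peak later than 2 minutes")
  plasma_input(t, conc)
}

rtrunc_norm <- function(n, mean, sd, lo = -2, hi = 2) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= lo | out >= hi))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Specification of a synthetic dynamic-PET cohort
#'
#' Defines the study conditions the generator emulates: cohort sizes, the
#' grouped dynamic frame protocol, true epileptogenic asymmetry of the 2TCM
#' micro-parameters (asymmetry of Ki and of static activity concentration
#' is never injected -- it emerges from the kinetics), physiological
#' parameter ranges, frame-duration-scaled Gaussian noise, and the
#' partial-volume truth used to build carotid measurements.
#'
#' @param n_patients,n_controls cohort sizes (defaults 17 and 8).
#' @param frame_groups dynamic protocol as (count, duration_s) groups;
#'   default the schedule of [default_frame_schedule()].
#' @param asym_mean named true mean asymmetry of the epileptogenic region
#'   per micro-parameter; defaults K1 = 0.12, k2 = 0.14, k3 = 0.21.
#' @param asym_sd named inter-patient sd of the injected asymmetry
#'   (default 0.05 each); draws are truncated to (-2, 2).
#' @param jitter_sd sd of the residual biological asymmetry given to
#'   controls and to non-epileptogenic regions (default 0.01).
#' @param param_lower,param_upper physiological ranges the contralateral
#'   (reference-side) micro-parameters are drawn from, uniformly.
#'   Defaults: K1 in [0.08, 0.12] mL min^-1 mL^-1, k2 in [0.10, 0.18],
#'   k3 in [0.04, 0.08] min^-1 (grey-matter FDG ranges).
#' @param vB_true true blood-volume fraction of the simulated tissue
#'   (default 0, matching the fitted model).
#' @param cv per-frame noise coefficient of variation at the reference
#'   frame duration (default 0.03); per-frame sd is
#'   `cv * value * sqrt(duration_ref / duration_f)`, the count-statistics
#'   scaling (longer frames are less noisy).
#' @param duration_ref_s reference frame duration at which `cv` is
#'   defined; default NULL = the protocol's shortest frame, so `cv` is
#'   the worst per-frame coefficient of variation across the scan.
#' @param rc,sp partial-volume truth used by the carotid mixer; when NULL
#'   both are derived from the point-spread phantom
#'   [estimate_rc_sp()]`(fwhm_mm, vessel_diameter_mm, roi_radius_mm)`.
#' @param fwhm_mm,vessel_diameter_mm,roi_radius_mm scanner/vessel/ROI
#'   geometry for that derivation (defaults 5.4, 6, 2 mm).
#' @param static_window_min late acquisition window emulating the static
#'   scan, minutes; default c(45, 60).
#' @param regions names of the six evaluation region pairs.
#' @param epi_weights relative frequency with which each region is the
#'   epileptogenic focus across patients; default (11, 2, 1, 1, 1, 1)
#'   matching the clinical distribution over hippocampus, inferior
#'   occipital, superior/middle frontal, orbital inferior frontal,
#'   supramarginal+angular, and insula.
#' @param dose_proxy,input_delay_min,amplitude_jitter_sd bolus settings
#'   passed to [simulate_input_function()].
#' @param seed master seed (mandatory); per-subject streams are derived
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 17L, n_controls = 8L,
                        frame_groups = list(c(12, 5), c(6, 10), c(6, 30),
                                            c(6, 120), c(10, 300)),
                        asym_mean = c(K1 = 0.12, k2 = 0.14, k3 = 0.21),
                        asym_sd = c(K1 = 0.05, k2 = 0.05, k3 = 0.05),
                        jitter_sd = 0.01,
                        param_lower = c(K1 = 0.08, k2 = 0.10, k3 = 0.04),
                        param_upper = c(K1 = 0.12, k2 = 0.18, k3 = 0.08),
                        vB_true = 0, cv = 0.03, duration_ref_s = NULL,
                        rc = NULL, sp = NULL, fwhm_mm = 5.4,
                        vessel_diameter_mm = 6, roi_radius_mm = 2,
                        static_window_min = c(45, 60),
                        regions = c("Hippocampus", "Occipital_Inf",
                                    "Frontal_Sup_Mid", "Frontal_Inf_Orb",
                                    "SupraMarginal_Angular", "Insula"),
                        epi_weights = c(11, 2, 1, 1, 1, 1),
                        dose_proxy = 1, input_delay_min = 0.5,
                        amplitude_jitter_sd = 0.1,
                        seed) {
  if (missing(seed) || !is.finite(seed))
    stop("spec error: a master seed is mandatory")
  par_names <- c("K1", "k2", "k3")
  asym_mean <- asym_mean[par_names]; asym_sd <- asym_sd[par_names]
  if (any(is.na(asym_mean)) || any(abs(asym_mean) >= 2))
    stop("spec error: asym means must be named K1,k2,k3 and lie in (-2, 2)")
  if (any(is.na(asym_sd)) || any(asym_sd < 0) || jitter_sd < 0)
    stop("spec error: asymmetry sds must be nonnegative")
  if (any(param_lower[par_names] <= 0) ||
      any(param_upper[par_names] < param_lower[par_names]))
    stop("spec error: parameter ranges must be positive and ordered")
  if (cv < 0) stop("spec error: negative noise CV")
  if (length(epi_weights) != length(regions) || any(epi_weights < 0))
    stop("spec error: epi_weights must be nonnegative, one per region")
  if (is.null(rc) || is.null(sp)) {
    est <- estimate_rc_sp(fwhm_mm, vessel_diameter_mm, roi_radius_mm)
    rc <- est$rc; sp <- est$sp
  }
  schedule <- make_frame_schedule(frame_groups)
  if (is.null(duration_ref_s)) duration_ref_s <- min(schedule$durations)
  if (duration_ref_s <= 0) stop("spec error: duration_ref_s must be positive")
  if (min_to_s(static_window_min[2]) > max(schedule$ends) ||
      static_window_min[1] >= static_window_min[2])
    stop("spec error: static window must be an ordered interval inside the scan")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    frame_groups = frame_groups, schedule = schedule,
    asym_mean = asym_mean, asym_sd = asym_sd, jitter_sd = jitter_sd,
    param_lower = param_lower[par_names], param_upper = param_upper[par_names],
    vB_true = vB_true, cv = cv, duration_ref_s = duration_ref_s,
    pvc = pvc_coefficients(rc, sp),
    fwhm_mm = fwhm_mm, vessel_diameter_mm = vessel_diameter_mm,
    roi_radius_mm = roi_radius_mm,
    static_window_min = static_window_min,
    regions = regions, epi_weights = epi_weights,
    dose_proxy = dose_proxy, input_delay_min = input_delay_min,
    amplitude_jitter_sd = amplitude_jitter_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

# deterministic assignment of each patient's epileptogenic region,
# following the configured frequency weights as closely as n allows
assign_epi_regions <- function(spec) {
  n <- spec$n_patients
  counts <- floor(spec$epi_weights / sum(spec$epi_weights) * n)
  while (sum(counts) < n) {
    frac <- spec$epi_weights / sum(spec$epi_weights) * n - counts
    counts[which.max(frac)] <- counts[which.max(frac)] + 1
  }
  rep(spec$regions, times = counts)[seq_len(n)]
}

#' Draw the ground-truth kinetics of one synthetic subject
#'
#' Contralateral (reference-side) micro-parameters are drawn uniformly
#' within the configured physiological ranges, independently per region.
#' The per-parameter true asymmetry `a` is drawn Normal(mean, sd)
#' truncated to (-2, 2) for the patient's epileptogenic region and
#' Normal(0, jitter_sd) elsewhere (and everywhere for controls); the
#' ipsilateral value is `contra * (2 - a) / (2 + a)`, the exact inverse of
#' the asymmetry index. True Ki per side follows via [compute_ki()]; true
#' static activity concentration is the late-window average of the
#' noiseless forward model. Ki and static-AC asymmetry are therefore
#' consequences of the injected micro-parameter kinetics, never injected
#' directly.
#'
#' @param spec a [cohort_spec()].
#' @param group `"patients"` or `"controls"`.
#' @param input the subject's true [plasma_input()].
#' @param epi_region region name carrying the injected asymmetry
#'   (patients only).
#' @param subject_id identifier copied into the rows.
#' @return data.frame with one row per region x side: columns
#'   `subject_id`, `group`, `region_id`, `region_class`, `side`
#'   (ipsilateral/contralateral; for controls the two physical sides in
#'   the same slots), `K1`, `k2`, `k3`, `vB`, `Ki`, `static_ac`.
#' @export
draw_subject_truth <- function(spec, group = c("patients", "controls"),
                               input, epi_region = NA_character_,
                               subject_id = "S01") {
  group <- match.arg(group)
  stopifnot(inherits(spec, "cohort_spec"), inherits(input, "plasma_input"))
  static_sched <- frame_schedule(min_to_s(spec$static_window_min[1]),
                                 min_to_s(diff(spec$static_window_min)))
  static_pred <- make_2tcm_predictor(input, static_sched)
  rows <- lapply(spec$regions, function(rg) {
    epi <- group == "patients" && identical(rg, epi_region)
    contra <- stats::setNames(
      stats::runif(3, spec$param_lower, spec$param_upper), c("K1", "k2", "k3"))
    a <- if (epi) {
      c(rtrunc_norm(1, spec$asym_mean[["K1"]], spec$asym_sd[["K1"]]),
        rtrunc_norm(1, spec$asym_mean[["k2"]], spec$asym_sd[["k2"]]),
        rtrunc_norm(1, spec$asym_mean[["k3"]], spec$asym_sd[["k3"]]))
    } else {
      rtrunc_norm(3, 0, spec$jitter_sd)
    }
    ipsi <- contra * (2 - a) / (2 + a)
    side_row <- function(side, p) {
      data.frame(subject_id = subject_id, group = group, region_id = rg,
                 region_class = if (epi) "epileptogenic" else "non_epileptogenic",
                 side = side, K1 = p[["K1"]], k2 = p[["k2"]], k3 = p[["k3"]],
                 vB = spec$vB_true,
                 Ki = compute_ki(p[["K1"]], p[["k2"]], p[["k3"]]),
                 static_ac = static_pred(p[["K1"]], p[["k2"]], p[["k3"]],
                                         spec$vB_true))
    }
    rbind(side_row("contralateral", contra), side_row("ipsilateral", ipsi))
  })
  do.call(rbind, rows)
}

#' Simulate the measured data of one synthetic subject
#'
#' Tissue TACs are the noiseless frame-averaged forward model plus
#' zero-mean Gaussian noise with per-frame sd
#' `cv * value * sqrt(duration_ref / duration_f)` (longer frames are less
#' noisy). The carotid measurement is built by [mix_carotid()] from the
#' true input and a background curve (the subject's average noiseless
#' tissue curve on the input's time base). Static activity concentration
#' is the late-window model mean plus noise at the reference CV.
#'
#' @param truth per-subject truth rows from [draw_subject_truth()].
#' @param spec a [cohort_spec()].
#' @param input the subject's true [plasma_input()].
#' @return list with `tacs` (long data.frame: subject_id, voi_id, side,
#'   frame_start_s, frame_duration_s, value_kBq_per_mL), `carotid`
#'   (a [carotid_measurement()]), `static` (data.frame: subject_id,
#'   voi_id, side, value_kBq_per_mL).
#' @export
simulate_subject_data <- function(truth, spec, input) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(input, "plasma_input"))
  sched <- spec$schedule
  pred <- make_2tcm_predictor(input, sched)
  dur <- sched$durations
  noise_fac <- sqrt(spec$duration_ref_s / dur)
  tac_rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    clean <- pred(tr$K1, tr$k2, tr$k3, tr$vB)
    noisy <- clean + stats::rnorm(sched$n, 0, spec$cv * clean * noise_fac)
    tac_rows[[i]] <- data.frame(
      subject_id = tr$subject_id, voi_id = tr$region_id, side = tr$side,
      frame_start_s = sched$starts, frame_duration_s = dur,
      value_kBq_per_mL = noisy)
  }
  # background: average tissue kinetics of this subject, instantaneous on
  # the input's own time base
  mp <- colMeans(truth[, c("K1", "k2", "k3")])
  bkgd <- forward_2tcm_curve(
    twotcm_params(mp[["K1"]], mp[["k2"]], mp[["k3"]], spec$vB_true),
    input, input$times_min)
  carotid <- mix_carotid(input, bkgd, spec$pvc)
  static <- truth[, c("subject_id", "region_id", "side")]
  names(static)[2] <- "voi_id"
  static$value_kBq_per_mL <- truth$static_ac +
    stats::rnorm(nrow(truth), 0, spec$cv * truth$static_ac)
  rownames(static) <- NULL
  list(tacs = do.call(rbind, tac_rows), carotid = carotid, static = static)
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject input functions, ground-truth kinetics and measured
#' data for `n_patients` patients and `n_controls` controls under one
#' master seed (per-subject child streams; identical seeds give
#' bit-identical cohorts).
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `pet_cohort`: list with `spec`, `subjects`
#'   (data.frame: subject_id, group, epi_region, seed), `truth` (stacked
#'   [draw_subject_truth()] rows), `tacs`, `static` (stacked data
#'   tables), `carotid` (named list of [carotid_measurement()]),
#'   `inputs` (named list of the true [plasma_input()]s, retained for
#'   validation), and `manifest`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients + spec$n_controls
  ids <- c(sprintf("P%02d", seq_len(spec$n_patients)),
           sprintf("C%02d", seq_len(spec$n_controls)))
  groups <- rep(c("patients", "controls"),
                c(spec$n_patients, spec$n_controls))
  epi <- c(assign_epi_regions(spec), rep(NA_character_, spec$n_controls))
  seeds <- with_local_seed(spec$seed, sample.int(2^31 - 2, n))
  dur_min <- s_to_min(max(spec$schedule$ends)) + 0.5
  truth <- vector("list", n); tacs <- vector("list", n)
  static <- vector("list", n)
  carotid <- vector("list", n); inputs <- vector("list", n)
  for (i in seq_len(n)) {
    input <- simulate_input_function(
      dose_proxy = spec$dose_proxy, duration_min = dur_min,
      delay_min = spec$input_delay_min, seed = seeds[i],
      amplitude_jitter_sd = spec$amplitude_jitter_sd)
    res <- with_local_seed(seeds[i] + 1L, {
      tr <- draw_subject_truth(spec, groups[i], input,
                               epi_region = epi[i], subject_id = ids[i])
      list(truth = tr, data = simulate_subject_data(tr, spec, input))
    })
    truth[[i]] <- res$truth
    tacs[[i]] <- res$data$tacs
    static[[i]] <- res$data$static
    carotid[[i]] <- res$data$carotid
    inputs[[i]] <- input
  }
  names(carotid) <- ids; names(inputs) <- ids
  structure(list(
    spec = spec,
    subjects = data.frame(subject_id = ids, group = groups,
                          epi_region = epi, seed = seeds),
    truth = do.call(rbind, truth),
    tacs = do.call(rbind, tacs),
    static = do.call(rbind, static),
    carotid = carotid, inputs = inputs,
    manifest = list(generator = "epikinet::simulate_cohort",
                    package_version = as.character(utils::packageVersion("epikinet")),
                    seed = spec$seed, subject_seeds = stats::setNames(seeds, ids),
                    n_patients = spec$n_patients, n_controls = spec$n_controls,
                    rc = spec$pvc$rc, sp = spec$pvc$sp, cv = spec$cv)),
    class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("pet_cohort: %d patients + %d controls, %d regions, CV %.1f%%, seed %d\n",
              x$spec$n_patients, x$spec$n_controls, length(x$spec$regions),
              100 * x$spec$cv, x$spec$seed))
  invisible(x)
}

#' True asymmetry table of a simulated cohort
#'
#' Recomputes, from the stored side values, the signed true asymmetry of
#' every parameter (K1, k2, k3, Ki, staticAC) per subject and region.
#'
#' @param cohort a `pet_cohort` from [simulate_cohort()].
#' @return long data.frame: subject_id, group, region_id, region_class,
#'   parameter, ipsi, contra, asym, abs_asym.
#' @export
truth_asym_table <- function(cohort) {
  tr <- cohort$truth
  wide <- merge(tr[tr$side == "ipsilateral",
                   c("subject_id", "group", "region_id", "region_class",
                     "K1", "k2", "k3", "Ki", "static_ac")],
                tr[tr$side == "contralateral",
                   c("subject_id", "region_id",
                     "K1", "k2", "k3", "Ki", "static_ac")],
                by = c("subject_id", "region_id"),
                suffixes = c("_ipsi", "_contra"))
  pars <- c(K1 = "K1", k2 = "k2", k3 = "k3", Ki = "Ki", staticAC = "static_ac")
  rows <- lapply(names(pars), function(p) {
    data.frame(subject_id = wide$subject_id, group = wide$group,
               region_id = wide$region_id, region_class = wide$region_class,
               parameter = p,
               ipsi = wide[[paste0(pars[[p]], "_ipsi")]],
               contra = wide[[paste0(pars[[p]], "_contra")]])
  })
  asym_table(do.call(rbind, rows))
}

#' Synthetic label atlas for round-trip testing
#'
#' A small 3D integer label volume whose labels are laid out as
#' left/right homologous pairs, plus the matching lookup table.
#'
#' @param dim volume dimensions, default c(20, 20, 10).
#' @param n_pairs number of homologous region pairs, default 6.
#' @return A [label_atlas()]; left labels are `1..n_pairs`, right labels
#'   `101..100+n_pairs`.
#' @export
make_synthetic_atlas <- function(dim = c(20, 20, 10), n_pairs = 6) {
  vol <- array(0L, dim)
  half <- floor(dim[1] / 2)
  zs <- round(seq(1, dim[3] + 1, length.out = n_pairs + 1))
  for (k in seq_len(n_pairs)) {
    zr <- zs[k]:(zs[k + 1] - 1)
    vol[seq_len(half), , zr] <- k
    vol[(dim[1] - half + 1):dim[1], , zr] <- 100L + k
  }
  lookup <- data.frame(
    label_id = c(seq_len(n_pairs), 100L + seq_len(n_pairs)),
    name = rep(paste0("region", seq_len(n_pairs)), 2),
    hemisphere = rep(c("left", "right"), each = n_pairs),
    homolog_id = c(100L + seq_len(n_pairs), seq_len(n_pairs)))
  label_atlas(vol, lookup)
}

#' Paint per-label curves into a labeled 4D volume
#'
#' Inverse of [extract_voi_tacs()]: writes each label's frame values into
#' all voxels carrying that label, producing a noiseless synthetic dynamic
#' volume (unlabelled voxels are 0).
#'
#' @param atlas a [label_atlas()].
#' @param values named list: `values[[as.character(label_id)]]` is the
#'   per-frame value vector for that label (length 1 for a static volume).
#' @return 4D array (or 3D when every vector has length 1).
#' @export
paint_volume <- function(atlas, values) {
  stopifnot(inherits(atlas, "label_atlas"))
  nf <- unique(vapply(values, length, integer(1)))
  if (length(nf) != 1L)
    stop("domain error: all painted curves must have the same length")
  dims <- dim(atlas$volume)
  out <- array(0, c(dims, nf))
  for (lab in names(values)) {
    idx <- which(atlas$volume == as.integer(lab))
    if (length(idx) == 0L)
      stop("empty-region error: label ", lab, " absent from atlas")
    for (f in seq_len(nf))
      out[idx + (f - 1) * prod(dims)] <- values[[lab]][f]
  }
  if (nf == 1L) array(out, dims) else out
}
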