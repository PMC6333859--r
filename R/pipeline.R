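#' Shared TAC-table I/O
#'
#' The delimited interchange format used throughout: one row per frame
#' with columns `subject_id`, `voi_id`, `side`, `frame_start_s`,
#' `frame_duration_s`, `value_kBq_per_mL`.
#'
#' @param df data.frame in the TAC-table layout.
#' @param path CSV path.
#' @return `read_tac_table` returns the data.frame; writers return `path`
#'   invisibly.
#' @export
write_tac_table <- function(df, path) {
  need <- c("subject_id", "voi_id", "side", "frame_start_s",
            "frame_duration_s", "value_kBq_per_mL")
  if (!all(need %in% names(df)))
    stop("data error: TAC table needs columns ", paste(need, collapse = ", "))
  utils::write.csv(df[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_table
#' @export
read_tac_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "voi_id", "side", "frame_start_s",
            "frame_duration_s", "value_kBq_per_mL")
  if (!all(need %in% names(df)))
    stop("data error: TAC table needs columns ", paste(need, collapse = ", "))
  df
}

#' Write a simulated cohort to a data directory
#'
#' Emits the shared table formats: `tacs.csv`, `carotid.csv` (subject_id,
#' time_min, cmeas, cbkgd), `static.csv`, `subjects.csv`, `truth.csv` and
#' `manifest.json`.
#'
#' @param cohort a `pet_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tac_table(cohort$tacs, file.path(dir, "tacs.csv"))
  car <- do.call(rbind, lapply(names(cohort$carotid), function(id) {
    cm <- cohort$carotid[[id]]
    data.frame(subject_id = id, time_min = cm$times_min,
               cmeas = cm$cmeas, cbkgd = cm$cbkgd)
  }))
  utils::write.csv(car, file.path(dir, "carotid.csv"), row.names = FALSE)
  utils::write.csv(cohort$static, file.path(dir, "static.csv"), row.names = FALSE)
  utils::write.csv(cohort$subjects[, c("subject_id", "group", "epi_region")],
                   file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort data directory
#'
#' Counterpart of [write_cohort()]; `truth.csv` is optional (real data
#' has none).
#'
#' @param dir data directory.
#' @return list with `tacs`, `carotid` (named list of
#'   [carotid_measurement()]), `static`, `subjects`, and `truth` (NULL if
#'   absent).
#' @export
read_cohort_data <- function(dir) {
  req <- c("tacs.csv", "carotid.csv", "static.csv", "subjects.csv")
  miss <- req[!file.exists(file.path(dir, req))]
  if (length(miss) > 0)
    stop("data error: missing cohort file(s): ", paste(miss, collapse = ", "))
  tacs <- read_tac_table(file.path(dir, "tacs.csv"))
  car <- utils::read.csv(file.path(dir, "carotid.csv"), stringsAsFactors = FALSE)
  carotid <- lapply(split(car, car$subject_id), function(d) {
    d <- d[order(d$time_min), ]
    carotid_measurement(d$time_min, d$cmeas, d$cbkgd)
  })
  static <- utils::read.csv(file.path(dir, "static.csv"), stringsAsFactors = FALSE)
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  tr_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tr_path))
    utils::read.csv(tr_path, stringsAsFactors = FALSE) else NULL
  list(tacs = tacs, carotid = carotid, static = static,
       subjects = subjects, truth = truth)
}

#' Pipeline run configuration
#'
#' @param seed master seed for the whole run (simulation and fitting).
#' @param simulate list of [cohort_spec()] arguments (without `seed`), or
#'   NULL when reading data from `data_dir`.
#' @param data_dir cohort data directory (see [read_cohort_data()]);
#'   ignored when `simulate` is given.
#' @param fit list of [fit_config()] arguments.
#' @param idif either `list(rc =, sp =)` or a geometry list
#'   `list(fwhm_mm =, vessel_diameter_mm =, roi_radius_mm =)` from which
#'   the coefficients are estimated via [estimate_rc_sp()].
#' @param fit_scope which TACs to fit: `"focus"` (patients' epileptogenic
#'   region; all evaluation regions for controls), `"patients_focus"`
#'   (patients' epileptogenic region only), or `"all"`.
#' @param stats list: `holm` (logical, apply Holm correction to the group
#'   tests; default FALSE, matching the convention of reporting
#'   uncorrected rank tests).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed, simulate = NULL, data_dir = NULL,
                       fit = list(), idif = NULL,
                       fit_scope = c("focus", "patients_focus", "all"),
                       stats = list(holm = FALSE)) {
  fit_scope <- match.arg(fit_scope)
  cfg <- list(seed = seed, simulate = simulate, data_dir = data_dir,
              fit = fit, idif = idif, fit_scope = fit_scope, stats = stats)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration against the config schema
#'
#' @param cfg a configuration list (e.g. parsed from YAML/JSON).
#' @return the config, invisibly; raises a `config error` otherwise.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config error: configuration must be a list")
  if (is.null(cfg$seed) || !is.finite(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config error: integer 'seed' is required")
  if (is.null(cfg$simulate) && is.null(cfg$data_dir))
    stop("config error: either 'simulate' or 'data_dir' must be given")
  if (!is.null(cfg$simulate) && !is.list(cfg$simulate))
    stop("config error: 'simulate' must be a list of cohort_spec arguments")
  if (!is.null(cfg$fit) && !is.list(cfg$fit))
    stop("config error: 'fit' must be a list of fit_config arguments")
  if (!is.null(cfg$idif)) {
    ok <- is.list(cfg$idif) &&
      (all(c("rc", "sp") %in% names(cfg$idif)) || "fwhm_mm" %in% names(cfg$idif))
    if (!ok)
      stop("config error: 'idif' must give rc+sp or a fwhm_mm geometry")
  }
  if (!is.null(cfg$fit_scope) &&
      !cfg$fit_scope %in% c("focus", "patients_focus", "all"))
    stop("config error: unknown fit_scope")
  invisible(cfg)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config error: config must be .yaml/.yml or .json"))
  cfg$simulate <- normalize_sim_args(cfg$simulate)
  do.call(run_config, cfg)
}

# YAML turns named vectors into lists; coerce the cohort_spec arguments
# that must be named numeric vectors back
normalize_sim_args <- function(sim) {
  if (is.null(sim)) return(NULL)
  for (f in c("asym_mean", "asym_sd", "param_lower", "param_upper"))
    if (!is.null(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
  if (!is.null(sim$frame_groups))
    sim$frame_groups <- lapply(sim$frame_groups, unlist)
  if (!is.null(sim$static_window_min))
    sim$static_window_min <- unlist(sim$static_window_min)
  sim
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

resolve_idif_coeff <- function(cfg, sim_spec = NULL) {
  if (!is.null(cfg$idif)) {
    if (all(c("rc", "sp") %in% names(cfg$idif)))
      return(pvc_coefficients(cfg$idif$rc, cfg$idif$sp))
    return(estimate_rc_sp(cfg$idif$fwhm_mm,
                          cfg$idif$vessel_diameter_mm %||% 6,
                          cfg$idif$roi_radius_mm %||% 2))
  }
  if (!is.null(sim_spec)) return(sim_spec$pvc)
  stop("config error: 'idif' coefficients required when reading external data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit every selected (subject, region, side) TAC of a cohort
#'
#' @param tacs long TAC table (shared format).
#' @param inputs named list of per-subject [plasma_input()] curves
#'   (typically corrected IDIFs).
#' @param schedule the [frame_schedule()] (must match the table's frames).
#' @param fitcfg a [fit_config()].
#' @return data.frame: subject_id, voi_id, side, K1, k2, k3, vB, Ki,
#'   wrss, converged.
#' @export
fit_cohort_tacs <- function(tacs, inputs, schedule, fitcfg = fit_config()) {
  keys <- unique(tacs[, c("subject_id", "voi_id", "side")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    d <- tacs[tacs$subject_id == k$subject_id & tacs$voi_id == k$voi_id &
                tacs$side == k$side, ]
    d <- d[order(d$frame_start_s), ]
    if (nrow(d) != schedule$n)
      stop("data error: subject ", k$subject_id, " region ", k$voi_id,
           " side ", k$side, " has ", nrow(d), " frames, expected ", schedule$n)
    tac <- tissue_tac(schedule, d$value_kBq_per_mL,
                      voi_id = k$voi_id, side = k$side)
    input <- inputs[[k$subject_id]]
    if (is.null(input))
      stop("data error: no input function for subject ", k$subject_id)
    fit <- fit_2tcm(tac, input, fitcfg)
    if (is.null(fit$params))
      stop("convergence failure: subject ", k$subject_id, " region ",
           k$voi_id, " side ", k$side)
    rows[[i]] <- data.frame(
      subject_id = k$subject_id, voi_id = k$voi_id, side = k$side,
      K1 = fit$params$K1, k2 = fit$params$k2, k3 = fit$params$k3,
      vB = fit$params$vB, Ki = fit$params$Ki, wrss = fit$wrss,
      converged = fit$converged)
  }
  do.call(rbind, rows)
}

# long asym-record table from fitted parameters + static concentrations
measured_asym_table <- function(fits, static, subjects) {
  static_w <- merge(
    static[static$side == "ipsilateral", c("subject_id", "voi_id", "value_kBq_per_mL")],
    static[static$side == "contralateral", c("subject_id", "voi_id", "value_kBq_per_mL")],
    by = c("subject_id", "voi_id"), suffixes = c("_ipsi", "_contra"))
  fits_w <- merge(
    fits[fits$side == "ipsilateral", c("subject_id", "voi_id", "K1", "k2", "k3", "Ki")],
    fits[fits$side == "contralateral", c("subject_id", "voi_id", "K1", "k2", "k3", "Ki")],
    by = c("subject_id", "voi_id"), suffixes = c("_ipsi", "_contra"))
  rows <- list()
  for (p in c("K1", "k2", "k3", "Ki")) {
    rows[[p]] <- data.frame(subject_id = fits_w$subject_id,
                            region_id = fits_w$voi_id, parameter = p,
                            ipsi = fits_w[[paste0(p, "_ipsi")]],
                            contra = fits_w[[paste0(p, "_contra")]])
  }
  rows$staticAC <- data.frame(subject_id = static_w$subject_id,
                              region_id = static_w$voi_id, parameter = "staticAC",
                              ipsi = static_w$value_kBq_per_mL_ipsi,
                              contra = static_w$value_kBq_per_mL_contra)
  long <- do.call(rbind, rows)
  long <- merge(long, subjects[, c("subject_id", "group", "epi_region")],
                by = "subject_id")
  long$region_class <- ifelse(!is.na(long$epi_region) &
                                long$region_id == long$epi_region,
                              "epileptogenic", "non_epileptogenic")
  long$epi_region <- NULL
  rownames(long) <- NULL
  asym_table(long)
}

parameter_order <- c("K1", "k2", "k3", "Ki", "staticAC")

# group-level statistics mirroring the study's reports
cohort_statistics <- function(asym, holm = FALSE) {
  asym$parameter <- factor(asym$parameter, levels = parameter_order)
  pat_epi <- asym[asym$group == "patients" & asym$region_class == "epileptogenic", ]
  means <- stats::aggregate(asym ~ parameter, pat_epi, mean)
  names(means)[2] <- "patients_epileptogenic_mean"

  # per-subject mean |asym| in non-epileptogenic regions, and for controls
  per_subj_abs <- function(d) {
    if (nrow(d) == 0) return(NULL)
    stats::aggregate(abs_asym ~ subject_id + parameter, d, mean)
  }
  ctl <- per_subj_abs(asym[asym$group == "controls", ])
  pat_ne <- per_subj_abs(asym[asym$group == "patients" &
                                asym$region_class == "non_epileptogenic", ])
  ctl_means <- if (!is.null(ctl))
    stats::aggregate(abs_asym ~ parameter, ctl, mean) else NULL
  if (!is.null(ctl_means)) names(ctl_means)[2] <- "controls_mean_abs"
  ne_means <- if (!is.null(pat_ne))
    stats::aggregate(abs_asym ~ parameter, pat_ne, mean) else NULL
  if (!is.null(ne_means)) names(ne_means)[2] <- "patients_nonepi_mean_abs"
  for (extra in list(ctl_means, ne_means))
    if (!is.null(extra)) means <- merge(means, extra, by = "parameter", all = TRUE)

  # patients (epileptogenic |asym|) vs controls (per-subject mean |asym|)
  group_tests <- NULL
  if (!is.null(ctl) && length(unique(ctl$subject_id)) >= 3 &&
      length(unique(pat_epi$subject_id)) >= 3) {
    group_tests <- do.call(rbind, lapply(parameter_order, function(p) {
      a <- abs(pat_epi$asym[pat_epi$parameter == p])
      b <- ctl$abs_asym[ctl$parameter == p]
      if (length(a) < 3 || length(b) < 3) return(NULL)
      cmp <- compare_groups(a, b, paired = FALSE)
      data.frame(comparison = "patients_epi_vs_controls", parameter = p,
                 test = cmp$test, method = cmp$method,
                 statistic = cmp$statistic, p_value = cmp$p_value,
                 mean_patients = cmp$mean_a, mean_controls = cmp$mean_b)
    }))
    if (!is.null(group_tests) && isTRUE(holm))
      group_tests$p_holm <- stats::p.adjust(group_tests$p_value, "holm")
  }

  # within-patient pairwise comparisons of epileptogenic ASYM across parameters
  pw <- NULL
  wide <- stats::reshape(pat_epi[, c("subject_id", "parameter", "asym")],
                         idvar = "subject_id", timevar = "parameter",
                         direction = "wide")
  names(wide) <- sub("^asym\\.", "", names(wide))
  have <- intersect(parameter_order, names(wide))
  if (nrow(wide) >= 3 && length(have) >= 2) {
    combs <- utils::combn(have, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      p1 <- combs[1, j]; p2 <- combs[2, j]
      ok <- stats::complete.cases(wide[, c(p1, p2)])
      if (sum(ok) < 3) return(NULL)
      cmp <- compare_groups(wide[ok, p1], wide[ok, p2], paired = TRUE)
      data.frame(parameter_a = p1, parameter_b = p2, test = cmp$test,
                 method = cmp$method, statistic = cmp$statistic,
                 p_value = cmp$p_value, mean_a = cmp$mean_a, mean_b = cmp$mean_b)
    }))
  }

  corr <- if (nrow(wide) >= 5 && length(have) >= 2)
    correlate_asym(wide[, have]) else NULL

  list(means = means, group_tests = group_tests, pairwise = pw,
       correlations = corr)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> IDIF correction -> 2TCM fits -> asymmetry
#' indices -> group statistics -> report, written as a reproducible run
#' directory: `manifest.json`, `data/` (simulated cohort tables),
#' `fits/fits.csv` + `fits/fits.json`, `asym.csv`,
#' `stats/{cohort_means,group_tests,pairwise_tests,correlations}.csv`,
#' `report.md`. Deterministic given config + seed. With `resume = TRUE`
#' an existing completed run with the same config hash is returned
#' untouched (no recomputation, no file rewritten).
#'
#' @param config a [run_config()] (or plain list validated by
#'   [validate_run_config()]).
#' @param out_dir run directory to create.
#' @param resume logical; reuse a completed identical run if present.
#' @return (invisibly) list with `cohort`/`data`, `idif_coeff`, `inputs`,
#'   `fits`, `asym`, `stats`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  validate_run_config(config)
  chash <- config_hash(unclass(config))
  man_path <- file.path(out_dir, "manifest.json")
  if (resume && file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    if (identical(man$config_hash, chash) && identical(man$status, "complete")) {
      res <- readRDS(file.path(out_dir, "run.rds"))
      return(invisible(res))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)

  simulated <- !is.null(config$simulate) && is.null(config$data_dir)
  if (simulated) {
    spec <- do.call(cohort_spec, c(config$simulate, list(seed = config$seed)))
    cohort <- simulate_cohort(spec)
    write_cohort(cohort, file.path(out_dir, "data"))
    data <- list(tacs = cohort$tacs, carotid = cohort$carotid,
                 static = cohort$static, subjects = cohort$subjects,
                 truth = cohort$truth)
    schedule <- spec$schedule
  } else {
    cohort <- NULL
    data <- read_cohort_data(config$data_dir)
    one <- data$tacs[data$tacs$subject_id == data$tacs$subject_id[1] &
                       data$tacs$voi_id == data$tacs$voi_id[1] &
                       data$tacs$side == data$tacs$side[1], ]
    one <- one[order(one$frame_start_s), ]
    schedule <- frame_schedule(one$frame_start_s, one$frame_duration_s)
    spec <- NULL
  }

  coeff <- resolve_idif_coeff(config, if (simulated) cohort$spec else NULL)
  inputs <- lapply(data$carotid, correct_idif, coeff = coeff)

  scope <- config$fit_scope %||% "focus"
  tacs <- data$tacs
  if (scope != "all") {
    sel <- merge(tacs, data$subjects, by = "subject_id")
    keep <- (sel$group == "patients" & !is.na(sel$epi_region) &
               sel$voi_id == sel$epi_region) |
      (scope == "focus" & sel$group == "controls")
    tacs <- sel[keep, names(tacs)]
  }
  if (nrow(tacs) == 0) stop("data error: no TACs selected for fitting")

  fitcfg <- do.call(fit_config, c(config$fit,
                                  if (is.null(config$fit$seed))
                                    list(seed = config$seed)))
  fits <- fit_cohort_tacs(tacs, inputs, schedule, fitcfg)
  static <- data$static[paste(data$static$subject_id, data$static$voi_id) %in%
                          paste(fits$subject_id, fits$voi_id), ]
  asym <- measured_asym_table(fits, static, data$subjects)
  st <- cohort_statistics(asym, holm = isTRUE(config$stats$holm))

  utils::write.csv(fits, file.path(out_dir, "fits", "fits.csv"), row.names = FALSE)
  jsonlite::write_json(fits, file.path(out_dir, "fits", "fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  utils::write.csv(asym, file.path(out_dir, "asym.csv"), row.names = FALSE)
  utils::write.csv(st$means, file.path(out_dir, "stats", "cohort_means.csv"),
                   row.names = FALSE)
  if (!is.null(st$group_tests))
    utils::write.csv(st$group_tests, file.path(out_dir, "stats", "group_tests.csv"),
                     row.names = FALSE)
  if (!is.null(st$pairwise))
    utils::write.csv(st$pairwise, file.path(out_dir, "stats", "pairwise_tests.csv"),
                     row.names = FALSE)
  if (!is.null(st$correlations)) {
    cm <- st$correlations
    utils::write.csv(data.frame(parameter = rownames(cm$rho), cm$rho),
                     file.path(out_dir, "stats", "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(parameter = rownames(cm$p), cm$p),
                     file.path(out_dir, "stats", "correlation_pvalues.csv"),
                     row.names = FALSE)
  }
  write_report_md(file.path(out_dir, "report.md"), st, coeff, config)

  res <- list(cohort = cohort, data = data, idif_coeff = coeff,
              inputs = inputs, fits = fits, asym = asym, stats = st,
              out_dir = out_dir)
  saveRDS(res, file.path(out_dir, "run.rds"))
  manifest <- list(status = "complete", config_hash = chash,
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("epikinet")),
                   rc = coeff$rc, sp = coeff$sp,
                   n_fits = nrow(fits))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(res)
}

write_report_md <- function(path, st, coeff, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Dynamic FDG-PET asymmetry pipeline report")
  w("")
  w("- IDIF partial-volume coefficients: RC = %.4f, SP = %.4f", coeff$rc, coeff$sp)
  w("- Master seed: %d", as.integer(config$seed))
  w("")
  w("## Cohort-mean asymmetry indices")
  w("")
  df <- st$means
  w(paste(c("parameter", names(df)[-1]), collapse = " | "))
  w(paste(rep("---", ncol(df)), collapse = " | "))
  for (i in seq_len(nrow(df)))
    w(paste(c(as.character(df$parameter[i]),
              sprintf("%.4f", as.numeric(df[i, -1]))), collapse = " | "))
  if (!is.null(st$group_tests)) {
    w("")
    w("## Patients (epileptogenic |ASYM|) vs controls (mean |ASYM|)")
    w("")
    for (i in seq_len(nrow(st$group_tests)))
      w("- %s: %s, p = %.4g", st$group_tests$parameter[i],
        st$group_tests$test[i], st$group_tests$p_value[i])
  }
  if (!is.null(st$pairwise)) {
    w("")
    w("## Within-patient pairwise parameter comparisons (epileptogenic ASYM)")
    w("")
    for (i in seq_len(nrow(st$pairwise)))
      w("- %s vs %s: signed-rank p = %.4g (means %.4f vs %.4f)",
        st$pairwise$parameter_a[i], st$pairwise$parameter_b[i],
        st$pairwise$p_value[i], st$pairwise$mean_a[i], st$pairwise$mean_b[i])
  }
  if (!is.null(st$correlations)) {
    w("")
    w("## Spearman correlations of epileptogenic ASYM across parameters")
    w("")
    rho <- st$correlations$rho
    w(paste(c("", colnames(rho)), collapse = " | "))
    w(paste(rep("---", ncol(rho) + 1), collapse = " | "))
    for (i in seq_len(nrow(rho)))
      w(paste(c(rownames(rho)[i], sprintf("%.3f", rho[i, ])), collapse = " | "))
  }
  invisible(path)
}
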