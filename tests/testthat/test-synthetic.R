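test_that("bolus input function: linearity, delay, closed-form shape", {
  t <- seq(0, 10, by = 0.01)
  base <- feng_curve(t)
  expect_equal(feng_curve(t, scale = 2), 2 * base)

  inp <- simulate_input_function(delay_min = 0.5)
  expect_true(all(inp$conc[inp$times_min < 0.5] == 0))
  expect_true(all(inp$conc >= 0))

  # peak location/value of the closed form: A1*s*exp(-l1*s) peaks at s = 1/l1
  pk_t <- inp$times_min[which.max(inp$conc)]
  s <- pk_t - 0.5
  expect_lt(abs(s - 1 / 4), 0.02)           # default l1 = 4 /min
  expect_lt(pk_t, 2)                        # bolus peak inside 2 min
  expect_equal(max(inp$conc), feng_curve(pk_t), tolerance = 1e-12)
  # peak/tail ratio from direct evaluation of the closed form
  expect_equal(max(inp$conc) / feng_curve(60),
               feng_curve(pk_t) / feng_curve(60))

  expect_error(simulate_input_function(dose_proxy = -1), "spec error")
})

test_that("truth draws invert the asymmetry index exactly", {
  # a = 0.5 on contra = 1.0 gives ipsi = 0.6 and round-trips
  a <- 0.5; contra <- 1.0
  ipsi <- contra * (2 - a) / (2 + a)
  expect_equal(ipsi, 0.6)
  expect_equal(asym_index(contra, ipsi), a)

  # zero injected asymmetry and zero jitter: perfect symmetry
  spec0 <- small_spec(n_patients = 2, asym_sd = c(K1 = 0, k2 = 0, k3 = 0),
                      jitter_sd = 0,
                      seed = 7)
  spec0$asym_mean <- c(K1 = 0, k2 = 0, k3 = 0)
  co <- simulate_cohort(spec0)
  ta <- truth_asym_table(co)
  expect_equal(ta$asym, rep(0, nrow(ta)), tolerance = 1e-12)
  expect_equal(co$truth$K1[co$truth$side == "ipsilateral"],
               co$truth$K1[co$truth$side == "contralateral"])

  # sd = 0 with the configured means: every patient's epileptogenic
  # micro-ASYM is exactly the configured mean
  spec1 <- small_spec(n_patients = 3, seed = 8)
  co1 <- simulate_cohort(spec1)
  ta1 <- truth_asym_table(co1)
  epi <- ta1[ta1$region_class == "epileptogenic", ]
  for (p in c("K1", "k2", "k3"))
    expect_equal(epi$asym[epi$parameter == p],
                 rep(unname(spec1$asym_mean[p]), 3), tolerance = 1e-12)
})

test_that("the stored truth reproduces its own asymmetry when recomputed", {
  spec <- small_spec(n_patients = 2, n_controls = 1, cv = 0.03,
                     asym_sd = c(K1 = 0.02, k2 = 0.02, k3 = 0.02),
                     jitter_sd = 0.01, seed = 33)
  co <- simulate_cohort(spec)
  ta <- truth_asym_table(co)
  expect_equal(ta$asym, asym_index(ta$contra, ta$ipsi))
  expect_equal(ta$abs_asym, abs(ta$asym))
})

test_that("CV = 0 data equal the noiseless forward model and IDIF round-trips", {
  spec <- small_spec(n_patients = 1, seed = 12)
  co <- simulate_cohort(spec)
  id <- co$subjects$subject_id[1]
  input <- co$inputs[[id]]
  tr <- co$truth[co$truth$region_id == "A" &
                   co$truth$side == "ipsilateral", ]
  tac <- co$tacs[co$tacs$voi_id == "A" & co$tacs$side == "ipsilateral", ]
  model <- forward_2tcm(twotcm_params(tr$K1, tr$k2, tr$k3, tr$vB),
                        input, spec$schedule)
  expect_equal(tac$value_kBq_per_mL, model$values, tolerance = 1e-12)

  # carotid mixing with known RC/SP inverts exactly at CV = 0
  rec <- correct_idif(co$carotid[[id]], spec$pvc)
  expect_equal(rec$conc, input$conc, tolerance = 1e-10)

  # static concentration is the late-window mean of the noiseless model
  stat <- co$static[co$static$voi_id == "A" &
                      co$static$side == "ipsilateral", ]
  win <- frame_schedule(min_to_s(spec$static_window_min[1]),
                        min_to_s(diff(spec$static_window_min)))
  late <- forward_2tcm(twotcm_params(tr$K1, tr$k2, tr$k3, tr$vB), input, win)
  expect_equal(stat$value_kBq_per_mL, late$values, tolerance = 1e-12)
})

test_that("cohorts are bit-identical under one seed and differ across seeds", {
  spec <- small_spec(n_patients = 2, n_controls = 1, cv = 0.05, seed = 99,
                     asym_sd = c(K1 = 0.02, k2 = 0.02, k3 = 0.02),
                     jitter_sd = 0.01)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$tacs, c2$tacs)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$static, c2$static)

  spec2 <- small_spec(n_patients = 2, n_controls = 1, cv = 0.05, seed = 100,
                      asym_sd = c(K1 = 0.02, k2 = 0.02, k3 = 0.02),
                      jitter_sd = 0.01)
  c3 <- simulate_cohort(spec2)
  expect_false(identical(c1$tacs$value_kBq_per_mL,
                         c3$tacs$value_kBq_per_mL))
})

test_that("controls' static |ASYM| shrinks monotonically to 0 with CV", {
  cvs <- c(0.10, 0.05, 0.02, 0)
  means <- vapply(cvs, function(cv) {
    spec <- small_spec(n_patients = 0, n_controls = 6, cv = cv, seed = 404,
                       regions = paste0("r", 1:6))
    co <- simulate_cohort(spec)
    st <- co$static
    w <- merge(st[st$side == "ipsilateral", c("subject_id", "voi_id", "value_kBq_per_mL")],
               st[st$side == "contralateral", c("subject_id", "voi_id", "value_kBq_per_mL")],
               by = c("subject_id", "voi_id"), suffixes = c("_i", "_c"))
    w$asym <- asym_index(w$value_kBq_per_mL_c, w$value_kBq_per_mL_i)
    w$parameter <- "staticAC"; w$region_id <- w$voi_id
    per <- vapply(split(w, w$subject_id), function(d)
      unname(control_mean_abs_asym(d, paste0("r", 1:6))), numeric(1))
    mean(per)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_equal(means[length(means)], 0, tolerance = 1e-12)
})

test_that("cohort spec validation rejects impossible study conditions", {
  expect_error(cohort_spec(), "seed")
  expect_error(small_spec(static_window_min = c(60, 45)), "spec error")
  expect_error(small_spec(cv = -0.1), "spec error")
  expect_error({
    s <- small_spec(); cohort_spec(asym_mean = c(K1 = 2.5, k2 = 0, k3 = 0),
                                   seed = 1)
  }, "spec error")
})
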