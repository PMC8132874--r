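test_that("degenerate forward model reproduces the true trajectory", {
  cohort <- cohort_config(1, duration_h = 48, seed = 3)
  b <- simulate_patient(ttm_protocol(), noiseless_params(), cohort, 99)
  core_hat <- compute_core_temp(b$ds$th1_c, b$ds$th2_c, heat_flux_model())
  expect_equal(core_hat, b$truth$core$core_c, tolerance = 1e-9)
  # reference reads the true core exactly at every tick
  idx <- match(b$ref$t_s, b$truth$core$t_s)
  expect_equal(b$ref$temp_c, b$truth$core$core_c[idx], tolerance = 1e-9)
  expect_equal(nrow(b$ref), 97)   # 48 h at 30 min, t = 0 included
  expect_length(b$truth$artifact_ticks, 0)
})

test_that("cohort simulation is deterministic and validated", {
  cfg <- cohort_config(3, duration_h = 30, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_length(a, 3)
  # different patients get different draws
  expect_false(a[[1]]$truth$sensor_bias == a[[2]]$truth$sensor_bias)
  expect_error(cohort_config(0), "n_patients")
  expect_error(cohort_config(2.5), "n_patients")
  expect_error(cohort_config(5, ds_rate_hz = 0), "> 0")
})

test_that("dropout segments blank the sensor stream only there", {
  cfg <- cohort_config(1, duration_h = 30, seed = 8)
  par <- noiseless_params(dropout_segments = list(c(3600, 7200)))
  b <- simulate_patient(ttm_protocol(), par, cfg, 5)
  expect_false(any(b$ds$t_s >= 3600 & b$ds$t_s <= 7200))
  expect_true(any(b$ds$t_s < 3600) && any(b$ds$t_s > 7200))
})

test_that("analysis results are invariant to the Ks/Kg ratio", {
  cfg <- cohort_config(2, duration_h = 30, seed = 21)
  d1 <- pair_cohort(simulate_cohort(cfg, model = heat_flux_model(0.2)),
                    model = heat_flux_model(0.2))
  d2 <- pair_cohort(simulate_cohort(cfg, model = heat_flux_model(5)),
                    model = heat_flux_model(5))
  expect_equal(d1$diff_c, d2$diff_c, tolerance = 1e-9)
})

test_that("per-patient bias is recovered from the paired differences", {
  cfg <- cohort_config(22, duration_h = 48, seed = 31)
  par <- patient_params(artifact_prob = 0)   # recovery on clean data
  coh <- simulate_cohort(cfg, params = par)
  within3 <- vapply(coh, function(b) {
    p <- pair_streams(b$ds, b$ref)
    se <- sd(p$diff_c) / sqrt(nrow(p))
    abs(mean(p$diff_c) - b$truth$sensor_bias) <= 3 * se
  }, TRUE)
  # the per-patient lag adds a small systematic offset during the
  # induction/rewarming ramps, so allow isolated exceedances
  expect_gte(mean(within3), 0.9)
})

test_that("pooled difference SD matches the calibrated dispersion", {
  # per-seed pooled SD inherits the sampling noise of the 20 realised
  # patient biases, so the calibration band is checked on the mean
  sds <- vapply(c(101, 202, 303, 404), function(seed) {
    cfg <- cohort_config(20, duration_h = 48, seed = seed)
    coh <- simulate_cohort(cfg, params = patient_params(artifact_prob = 0))
    sd(pair_cohort(coh)$diff_c)
  }, numeric(1))
  expect_true(all(sds > 0.3 & sds < 0.8))
  expect_gte(mean(sds), 0.45)
  expect_lte(mean(sds), 0.62)
})

test_that("parameter validation rejects impossible configurations", {
  expect_error(patient_params(ds_noise_sd = -1), "SD")
  expect_error(patient_params(artifact_prob = 1.5), "artifact_prob")
  expect_error(patient_params(jitter_ar = 1), "jitter_ar")
  expect_error(patient_params(dropout_segments = list(c(5, 2))),
               "dropout_segments")
})
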