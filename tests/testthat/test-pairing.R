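test_that("window-mean pairing matches hand-computed values", {
  m <- heat_flux_model(0.5)
  # constant stream: every pair equals the constant
  s <- forward_skin_temps(33, 1, m)
  ds <- dual_sensor_stream(0:7200, rep(s$th1, 7201), rep(s$th2, 7201))
  ref <- reference_stream(c(600, 3000, 6000), rep(33, 3))
  p <- pair_streams(ds, ref, m)
  expect_equal(nrow(p), 3)
  expect_equal(p$ds_core_c, rep(33, 3), tolerance = 1e-12)
  expect_equal(p$diff_c, p$ds_core_c - p$ref_c)

  # linear ramp 33 -> 34 over 3600 s, tick mid-span, 60 s window:
  # symmetric window on a linear ramp averages to the midpoint value
  core <- 33 + (0:3600) / 3600
  s <- forward_skin_temps(core, 1, m)
  ds <- dual_sensor_stream(0:3600, s$th1, s$th2)
  p <- pair_streams(ds, reference_stream(1800, 33.5), m, window_s = 60)
  expect_equal(p$ds_core_c, 33.5, tolerance = 1e-12)

  # nearest-sample mode picks the closest reading
  p2 <- pair_streams(ds, reference_stream(1800.4, 33.5), m,
                     window_s = 60, method = "nearest")
  expect_equal(p2$ds_core_c, core[1801], tolerance = 1e-12)
})

test_that("non-overlapping streams yield an empty dataset with a warning", {
  m <- heat_flux_model(0.5)
  s <- forward_skin_temps(33, 1, m)
  ds <- dual_sensor_stream(0:100, rep(s$th1, 101), rep(s$th2, 101))
  ref <- reference_stream(c(5000, 6000), c(33, 33))
  expect_warning(p <- pair_streams(ds, ref, m), "overlap")
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "skipped_ticks"), 2L)
  expect_error(pair_streams(ds, ref, m, window_s = 0), "window_s")
})

test_that("2-SD filter flags exactly the hand-computed outlier", {
  diffs <- c(rep(0.1, 19), 5)
  m <- mean(diffs); s <- sd(diffs)
  expect_true(abs(5 - m) > 2 * s && abs(0.1 - m) <= 2 * s) # corridor check
  flagged <- remove_artifacts(make_paired(diffs))
  expect_identical(which(flagged$artifact), 20L)
  cts <- attr(flagged, "counts")
  expect_equal(unname(cts), c(20, 1, 19))
  expect_equal(unname(cts["retained"] + cts["artifacts"]), unname(cts["total"]))
  expect_equal(nrow(retained(flagged)), 19)
  expect_false(any(retained(flagged)$artifact))
})

test_that("degenerate and undersized inputs are handled per contract", {
  # equal differences: SD = 0, nothing can exceed the corridor
  flagged <- remove_artifacts(make_paired(rep(0.2, 10)))
  expect_equal(sum(flagged$artifact), 0)
  expect_error(remove_artifacts(make_paired(c(0.1, 0.2))), "fewer than 3")
})

test_that("filter variants: zero-centred and per-patient corridors", {
  set.seed(44)
  diffs <- c(rnorm(50, 1, 0.05), -1)  # strong common offset, one outlier
  z <- remove_artifacts(make_paired(diffs), center = "zero")
  m <- remove_artifacts(make_paired(diffs), center = "mean")
  # zero-centred corridor keeps the offset cluster flaggable differently
  expect_false(identical(z$artifact, m$artifact))

  two <- make_paired(c(rnorm(30, 0, 0.1), rnorm(30, 2, 0.1)))
  two$patient <- rep(1:2, each = 30)
  pooled <- remove_artifacts(two)
  per <- remove_artifacts(two, by_patient = TRUE)
  expect_error(remove_artifacts(make_paired(rnorm(10)), by_patient = TRUE),
               "patient")
  expect_true(is.logical(per$artifact) && is.logical(pooled$artifact))
})

test_that("clean Gaussian differences are flagged near the 2-SD rate", {
  set.seed(7)
  rates <- replicate(30, {
    f <- remove_artifacts(make_paired(rnorm(1319, 0.02, 0.53)))
    unname(attr(f, "counts")["artifacts"]) / 1319
  })
  expect_lt(abs(mean(rates) * 100 - 4.55), 1.5)
})

test_that("injected artifact epochs are flagged at the mixture-model rate", {
  # with shocks ~ N(0, 3) on a baseline diff SD s0, the pooled corridor
  # is 2 * sqrt((1-p) s0^2 + p (s0^2 + 3^2)) and detection is the
  # normal tail beyond it -- well above the clean rate, but bounded
  s0 <- 0.48; p <- 0.05; mag <- 3
  s_pool <- sqrt((1 - p) * s0^2 + p * (s0^2 + mag^2))
  p_detect <- 2 * pnorm(-2 * s_pool / sqrt(s0^2 + mag^2))
  set.seed(12)
  hits <- replicate(40, {
    n <- 1319
    art <- runif(n) < p
    d <- rnorm(n, 0, s0) + ifelse(art, rnorm(n, 0, mag), 0)
    f <- remove_artifacts(make_paired(d))
    c(sum(f$artifact & art), sum(art))
  })
  rate <- sum(hits[1, ]) / sum(hits[2, ])
  expect_lt(abs(rate - p_detect), 0.06)
  expect_gt(rate, 0.5)   # far more sensitive than the 4.55% clean rate
})
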