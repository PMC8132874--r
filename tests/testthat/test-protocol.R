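test_that("noiseless trajectory follows the protocol exactly", {
  p <- ttm_protocol()
  tr <- protocol_trajectory(p, duration_h = 48, step_s = 60, jitter_sd = 0)
  ind_end_h <- (35.5 - 33) / 1.5
  # maintenance plateau is exactly the target
  at <- tr$t_s / 3600 >= ind_end_h + 1 & tr$t_s / 3600 <= ind_end_h + 23
  expect_true(all(tr$core_c[at] == 33))
  # rewarming spans (37 - 33) / 0.25 = 16 h and ends at 37
  rew_start <- ind_end_h + 24
  expect_equal(tr$core_c[which.min(abs(tr$t_s / 3600 - (rew_start + 16)))],
               37)
  # slope during rewarming is exactly 0.25 C/h
  rew <- tr$t_s / 3600 > rew_start & tr$t_s / 3600 < rew_start + 16
  slopes <- diff(tr$core_c[rew]) / diff(tr$t_s[rew] / 3600)
  expect_equal(unique(round(slopes, 12)), 0.25)
  # after reaching the post-target the trajectory holds there
  post <- tr$t_s / 3600 > rew_start + 16
  expect_true(all(tr$core_c[post] == 37))
})

test_that("noiseless trajectory is continuous and piecewise linear", {
  tr <- protocol_trajectory(ttm_protocol(), duration_h = 48, step_s = 30,
                            jitter_sd = 0)
  d2 <- diff(tr$core_c, differences = 2)
  # second differences vanish except at the three phase joints
  expect_lte(sum(abs(d2) > 1e-9), 3)
  # continuity: no step exceeds the fastest rate times the grid step
  expect_lte(max(abs(diff(tr$core_c))), 1.5 * 30 / 3600 + 1e-12)
})

test_that("trajectory grid and jitter behave as configured", {
  tr <- protocol_trajectory(ttm_protocol(), duration_h = 48, step_s = 1800,
                            jitter_sd = 0)
  expect_equal(nrow(tr), 97)         # 48 h at 30 min including t = 0
  expect_equal(tr$t_s[1], 0)
  set.seed(5)
  trj <- protocol_trajectory(ttm_protocol(), duration_h = 48, step_s = 60)
  expect_false(all(trj$core_c[trj$t_s > 10 * 3600 &
                                trj$t_s < 20 * 3600] == 33))
  # marginal jitter SD close to nominal on the long plateau
  plateau <- trj$core_c[trj$t_s / 3600 > 3 & trj$t_s / 3600 < 25] - 33
  expect_lt(abs(sd(plateau) - 0.05), 0.035)
})

test_that("protocol and trajectory inputs are validated", {
  expect_error(ttm_protocol(rewarm_rate = 0), "rate")
  expect_error(ttm_protocol(target_temp = 38), "post_target")
  expect_error(ttm_protocol(maintenance_h = -1), "durations")
  expect_error(protocol_trajectory(ttm_protocol(), step_s = 0), "step_s")
  expect_error(protocol_trajectory(ttm_protocol(), duration_h = 10),
               "cover")
  expect_equal(protocol_duration_h(ttm_protocol()),
               (35.5 - 33) / 1.5 + 24 + 16 + 24)
})
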