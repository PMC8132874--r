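test_that("paired t statistic matches hand arithmetic and stats::t.test", {
  r <- paired_t_test(c(0, 0.5, -0.5, 0.2, -0.2))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  r <- paired_t_test(c(1, 1, 2))       # mean 4/3, sd 1/sqrt(3)
  expect_equal(r$t_stat, 4)
  set.seed(9)
  d <- rnorm(40, 0.1, 0.5)
  r <- paired_t_test(d)
  ref <- t.test(d)
  expect_equal(r$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(paired_t_test(1), "at least 2")
  expect_error(paired_t_test(rep(0.3, 5)), "zero SD")
})

test_that("Bland-Altman statistics match hand arithmetic", {
  r <- bland_altman(c(-1, 0, 1))
  expect_equal(r$bias, 0)
  expect_equal(r$sd, 1)
  expect_equal(r$loa_low, -1.96)
  expect_equal(r$loa_high, 1.96)
  tq <- qt(0.975, 2)
  expect_equal(r$bias_ci, c(-tq / sqrt(3), tq / sqrt(3)))
  se_loa <- sqrt(1 / 3 + 1.96^2 / 4)
  expect_equal(r$loa_low_ci, -1.96 + c(-1, 1) * tq * se_loa)

  r0 <- bland_altman(rep(0, 5))
  expect_equal(c(r0$bias, r0$sd, r0$loa_low, r0$loa_high), c(0, 0, 0, 0))
  expect_error(bland_altman(c(0, 1)), "at least 3")
})

test_that("LoA midpoint and width identities hold on random inputs", {
  set.seed(13)
  for (i in 1:20) {
    d <- rnorm(sample(5:500, 1), rnorm(1), runif(1, 0.1, 2))
    r <- bland_altman(d)
    expect_equal((r$loa_low + r$loa_high) / 2, r$bias, tolerance = 1e-12)
    expect_equal(r$loa_high - r$loa_low, 2 * 1.96 * r$sd,
                 tolerance = 1e-12)
  }
})

test_that("consistency ICC is exact on degenerate tables", {
  x <- c(1, 2, 3, 4, 5, 6)
  r <- icc_consistency(x, x)
  expect_equal(r$icc, 1)
  # constant offset between raters does not reduce consistency ICC
  r <- icc_consistency(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(r$icc, 1)
  expect_error(icc_consistency(rep(1, 6), rep(1, 6)), "identical")
  expect_error(icc_consistency(1:4, 1:4), "at least 5")
})

test_that("F-method ICC equals the ANOVA sum-of-squares oracle", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    s <- rnorm(n, 34, runif(1, 0.5, 2))
    mat <- cbind(s + rnorm(n, 0, 0.4), s + rnorm(n, 0.2, 0.4))
    r <- icc_consistency(mat[, 1], mat[, 2])
    expect_equal(r$icc, aov_icc_oracle(mat, "consistency"),
                 tolerance = 1e-10)
    ra <- icc_consistency(mat[, 1], mat[, 2], type = "agreement")
    expect_equal(ra$icc, aov_icc_oracle(mat, "agreement"),
                 tolerance = 1e-10)
    expect_lte(r$icc_ci[1], r$icc)
    expect_gte(r$icc_ci[2], r$icc)
  }
})

test_that("ICC converges to the variance-ratio limit", {
  set.seed(31)
  n <- 10000
  s <- rnorm(n, 0, 1)          # sigma_b^2 = 1
  e_sd <- 0.5                  # sigma_e^2 = 0.25 -> ICC = 0.8
  r <- icc_consistency(s + rnorm(n, 0, e_sd), s + rnorm(n, 0, e_sd))
  expect_lt(abs(r$icc - 1 / 1.25), 0.01)
})

test_that("Cicchetti classification covers all boundaries", {
  expect_equal(classify_icc(0.94), "excellent")
  expect_equal(classify_icc(0.75), "excellent")
  expect_equal(classify_icc(0.745), "good")
  expect_equal(classify_icc(0.60), "good")
  expect_equal(classify_icc(0.595), "moderate")
  expect_equal(classify_icc(0.40), "moderate")
  expect_equal(classify_icc(0.39), "poor")
  expect_equal(classify_icc(-0.2), "poor")
  expect_error(classify_icc(NA_real_), "finite")
})

test_that("threshold coverage counts inclusively and converges", {
  expect_equal(pct_within_threshold(c(0, 0, 0), 0.5), 100)
  expect_equal(pct_within_threshold(c(0.1, 0.6, -0.4), 0.5), 200 / 3)
  expect_equal(pct_within_threshold(0.5, 0.5), 100)   # boundary inclusive
  expect_error(pct_within_threshold(numeric(0)), "empty")
  expect_error(pct_within_threshold(c(0.1), 0), "threshold")
  # Gaussian closed form at the printed bias/SD
  set.seed(41)
  d <- rnorm(1e5, 0.02, 0.53)
  expected <- 100 * (pnorm((0.5 - 0.02) / 0.53) - pnorm((-0.5 - 0.02) / 0.53))
  expect_lt(abs(pct_within_threshold(d, 0.5) - expected), 0.5)
})

test_that("paired t-test keeps its nominal type-I error", {
  set.seed(47)
  rejections <- replicate(1000, {
    paired_t_test(rnorm(60, 0, 0.5))$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("method_agreement fit satisfies the report invariants", {
  set.seed(53)
  truth <- rnorm(300, 34.1, 1.5)
  fit <- method_agreement(truth + rnorm(300, 0.02, 0.375),
                          truth + rnorm(300, 0, 0.375))
  expect_s3_class(fit, "method_agreement")
  expect_equal((fit$loa_low + fit$loa_high) / 2, fit$bias,
               tolerance = 1e-12)
  expect_equal(fit$loa_high - fit$loa_low, 3.92 * fit$sd,
               tolerance = 1e-12)
  expect_true(fit$icc_ci[1] <= fit$icc && fit$icc <= fit$icc_ci[2])
  expect_true(fit$pct_within >= 0 && fit$pct_within <= 100)
  expect_equal(fit$icc_class, classify_icc(fit$icc))
  expect_equal(coef(fit)[["bias"]], fit$bias)
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-12)
  expect_output(print(fit), "ICC")
  expect_output(summary(fit), "LoA CIs")
})

test_that("agreement reports serialise and reparse without loss", {
  set.seed(59)
  truth <- rnorm(50, 34, 1.5)
  fit <- method_agreement(truth + rnorm(50, 0, 0.4),
                          truth + rnorm(50, 0, 0.4))
  path <- tempfile(fileext = ".json")
  write_agreement_report(fit, path, text = TRUE)
  back <- read_agreement_report(path)
  for (f in c("n", "bias", "sd", "loa_low", "loa_high", "t_stat",
              "p_value", "icc", "pct_within"))
    expect_equal(back[[f]], fit[[f]], tolerance = 1e-12)
  expect_equal(back$icc_ci, fit$icc_ci, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".txt")))
})
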