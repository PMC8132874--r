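# Build a paired dataset directly from a difference vector, bypassing
# the stream machinery, for tests of the filter and the statistics.
make_paired <- function(diffs, ref_level = 34) {
  out <- data.frame(t_s = seq_along(diffs) * 1800,
                    ds_core_c = ref_level + diffs,
                    ref_c = rep(ref_level, length(diffs)),
                    diff_c = diffs,
                    artifact = rep(FALSE, length(diffs)))
  structure(out, skipped_ticks = 0L, filtered = FALSE,
            class = c("paired_dataset", "data.frame"))
}

# Parameters that switch every stochastic element of the simulator off.
noiseless_params <- function(...) {
  patient_params(sensor_bias_sd = 0, lag_max_min = 0, ds_noise_sd = 0,
                 oet_noise_sd = 0, artifact_prob = 0, jitter_sd = 0,
                 ambient_sd = 0, ...)
}

# Independent ICC oracle: two-way ANOVA mean squares via stats::aov,
# then the Shrout-Fleiss / McGraw-Wong single-measure formulas.
aov_icc_oracle <- function(mat, type = "consistency") {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(y = as.vector(mat),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (type == "consistency") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Monte-Carlo power oracle for the ICC reliability test: simulate
# two-rater studies with true ICC p1 and apply the one-sided F test of
# H0: ICC = p0 at level alpha. Vectorised over simulations.
mc_icc_power <- function(n, p0, p1, alpha = 0.05, nsim = 4000) {
  s <- matrix(stats::rnorm(n * nsim, 0, sqrt(p1)), n)
  x <- s + matrix(stats::rnorm(n * nsim, 0, sqrt(1 - p1)), n)
  y <- s + matrix(stats::rnorm(n * nsim, 0, sqrt(1 - p1)), n)
  m <- (x + y) / 2
  d <- x - y
  msb <- 2 * colSums(sweep(m, 2, colMeans(m))^2) / (n - 1)
  mse <- colSums(sweep(d, 2, colMeans(d))^2) / (2 * (n - 1))
  crit <- (1 + p0) / (1 - p0) * stats::qf(1 - alpha, n - 1, n - 1)
  mean(msb / mse > crit)
}
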