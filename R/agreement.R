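#' Paired t-test on method differences
#'
#' Classical paired-samples t statistic on the differences `d`:
#' `t = mean(d) / (sd(d)/sqrt(n))` with the n-1 sample SD, and a
#' two-sided p-value from the t distribution on n-1 degrees of freedom.
#' A zero-SD input is rejected (the statistic is undefined); callers
#' wanting to assert a zero bias on constant differences should test
#' the mean directly.
#'
#' @param diffs Numeric vector of paired differences, degrees C.
#' @return A list with `t_stat`, `p_value`, `n`.
#' @export
paired_t_test <- function(diffs) {
  if (any(!is.finite(diffs))) stop("non-finite difference", call. = FALSE)
  n <- length(diffs)
  if (n < 2L) stop("paired t-test needs at least 2 differences",
                   call. = FALSE)
  s <- stats::sd(diffs)
  if (s == 0) stop("zero SD: paired t statistic undefined", call. = FALSE)
  t_stat <- mean(diffs) / (s / sqrt(n))
  list(t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1), n = n)
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean difference, the 95% limits of agreement are
#' `bias +/- 1.96 * SD` (the conventional normal-quantile multiplier,
#' not the t quantile), the bias CI uses the exact t quantile on n-1
#' degrees of freedom, and each limit's CI uses Bland and Altman's
#' standard-error approximation
#' `SE(LoA) = SD * sqrt(1/n + z^2 / (2(n-1)))`.
#'
#' @param diffs Numeric vector of paired differences (n >= 3).
#' @param alpha Two-sided CI level complement (default 0.05).
#' @param loa_mult Limits-of-agreement multiplier (default 1.96).
#' @return A list with `n`, `bias`, `sd`, `bias_ci`, `loa_low`,
#'   `loa_high`, `loa_low_ci`, `loa_high_ci`.
#' @export
bland_altman <- function(diffs, alpha = 0.05, loa_mult = 1.96) {
  if (any(!is.finite(diffs))) stop("non-finite difference", call. = FALSE)
  n <- length(diffs)
  if (n < 3L) stop("Bland-Altman needs at least 3 differences",
                   call. = FALSE)
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + loa_mult^2 / (2 * (n - 1)))
  loa_low <- bias - loa_mult * s
  loa_high <- bias + loa_mult * s
  list(n = n, bias = bias, sd = s,
       bias_ci = c(bias - tq * se_bias, bias + tq * se_bias),
       loa_low = loa_low, loa_high = loa_high,
       loa_low_ci = c(loa_low - tq * se_loa, loa_low + tq * se_loa),
       loa_high_ci = c(loa_high - tq * se_loa, loa_high + tq * se_loa))
}

# two-way ANOVA mean squares for an n x k complete table
two_way_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(n = n, k = k,
       msr = ss_rows / (n - 1),
       msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)))
}

#' Intraclass correlation for two-way designs, single measure
#'
#' Single-rating ICC from the two-way mean-square decomposition of an
#' n-subject by k-rater table. The default, `type = "consistency"`, is
#' the two-way mixed-effects consistency ICC — ICC(3,1) in
#' Shrout-Fleiss notation, C,1 in McGraw-Wong —
#' `(MSR - MSE) / (MSR + (k-1) MSE)`, which ignores a fixed offset
#' between raters. Its confidence interval is the exact F method: with
#' `F = MSR/MSE` on `(n-1, (n-1)(k-1))` degrees of freedom,
#' `lower = (F/Fu - 1)/(F/Fu + k - 1)` and
#' `upper = (F*Fl - 1)/(F*Fl + k - 1)` where `Fu`, `Fl` are the upper
#' alpha/2 quantiles for the two df orders.
#'
#' `type = "agreement"` gives the absolute-agreement single-measure ICC
#' (A,1 / ICC(2,1) form) with the McGraw-Wong Satterthwaite CI, offered
#' for sensitivity analysis.
#'
#' @param x,y The two aligned measurement vectors (one per rater), or
#'   `x` an n x k matrix with `y` omitted.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param alpha CI level complement (default 0.05 for a 95% CI).
#' @return A list with `icc`, `icc_ci` (length-2 vector), `type`, `n`,
#'   `k`, and the mean squares `msr`, `msc`, `mse`.
#' @examples
#' set.seed(1)
#' s <- rnorm(30, 34, 1.5)
#' icc_consistency(s + rnorm(30, 0, 0.4), s + rnorm(30, 0, 0.4))$icc
#' @export
icc_consistency <- function(x, y = NULL,
                            type = c("consistency", "agreement"),
                            alpha = 0.05) {
  type <- match.arg(type)
  mat <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (any(!is.finite(mat))) stop("non-finite measurement", call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 5L) stop("ICC needs at least 5 subjects", call. = FALSE)
  if (k < 2L) stop("ICC needs at least 2 raters", call. = FALSE)
  ms <- two_way_ms(mat)
  if (ms$msr + ms$mse == 0)
    stop("all measurements identical: ICC undefined", call. = FALSE)
  if (type == "consistency") {
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    f_obs <- ms$msr / ms$mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fu <- stats::qf(1 - alpha / 2, df1, df2)
    fl <- stats::qf(1 - alpha / 2, df2, df1)
    lo <- (f_obs / fu - 1) / (f_obs / fu + k - 1)
    hi <- (f_obs * fl - 1) / (f_obs * fl + k - 1)
  } else {
    icc <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    f_lo <- stats::qf(1 - alpha / 2, n - 1, v)
    f_hi <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - f_lo * ms$mse) /
      (f_lo * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (f_hi * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_hi * ms$msr)
  }
  list(icc = icc, icc_ci = c(lo, hi), type = type, n = n, k = k,
       msr = ms$msr, msc = ms$msc, mse = ms$mse)
}

#' Cicchetti reliability classification of an ICC
#'
#' Labels an ICC by the conventional Cicchetti cutoffs. The published
#' cutpoints leave the intervals (0.59, 0.6) and (0.74, 0.75)
#' unclassified; the half-open convention used here — poor \[0, 0.4),
#' moderate \[0.4, 0.6), good \[0.6, 0.75), excellent \[0.75, 1\] —
#' covers those gaps consistently. Negative ICCs are "poor".
#'
#' @param icc A finite ICC value.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @examples
#' classify_icc(0.94) # "excellent"
#' @export
classify_icc <- function(icc) {
  if (!is.numeric(icc) || length(icc) != 1L || !is.finite(icc))
    stop("'icc' must be a single finite number", call. = FALSE)
  if (icc < 0.4) "poor"
  else if (icc < 0.6) "moderate"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Percentage of differences within an a-priori threshold
#'
#' Share of paired differences with `|d| <= threshold`, in percent.
#' The boundary is inclusive (a difference of exactly the threshold
#' counts as within). The conventional a-priori acceptability limit for
#' core-temperature method comparison is +/- 0.5 degrees C, the
#' magnitude of normal circadian variation.
#'
#' @param diffs Non-empty numeric vector of differences, degrees C.
#' @param threshold Acceptability threshold, degrees C (> 0).
#' @return Percentage in \[0, 100\].
#' @export
pct_within_threshold <- function(diffs, threshold = 0.5) {
  if (length(diffs) == 0L) stop("empty difference vector", call. = FALSE)
  if (any(!is.finite(diffs))) stop("non-finite difference", call. = FALSE)
  if (!(threshold > 0)) stop("'threshold' must be > 0", call. = FALSE)
  100 * mean(abs(diffs) <= threshold)
}
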