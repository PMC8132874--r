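#' Power of the ICC reliability test
#'
#' Exact F-distribution power for testing `H0: ICC = p0` against
#' `H1: ICC = p1 > p0` in a design with `n` subjects and `k` ratings
#' each. With `F_obs = MSB/MSE` on `(n-1, (n-1)(k-1))` degrees of
#' freedom and `C(p) = (1 + (k-1)p) / (1-p)`, the level-alpha test
#' rejects when `F_obs > C(p0) * F_crit`; under a true ICC of `p1`,
#' `F_obs / C(p1)` is central F, so the power has the closed form
#' `1 - pf(C(p0)/C(p1) * F_crit, n-1, (n-1)(k-1))`. This is the
#' F-distribution method standard ICC sample-size calculators
#' implement; no normal approximation is involved.
#'
#' The hypothesis is directional (reliability at least `p0`), so
#' `alpha` is one-sided by default; `two_sided = TRUE` spends
#' `alpha/2`, matching a test by the two-sided confidence interval's
#' lower bound.
#'
#' @param n Number of subjects (>= k + 1).
#' @param p0 Null ICC, in \[0, 1).
#' @param p1 Alternative (anticipated) ICC, `p0 < p1 < 1`.
#' @param alpha Test level (default 0.05).
#' @param k Ratings per subject (default 2).
#' @param two_sided Spend `alpha/2` (test via a two-sided CI bound).
#' @return Achieved power in (0, 1).
#' @export
icc_power <- function(n, p0, p1, alpha = 0.05, k = 2, two_sided = FALSE) {
  check_power_spec(p0, p1, alpha, k)
  if (any(n < k + 1)) stop("'n' must be at least k + 1", call. = FALSE)
  a <- if (two_sided) alpha / 2 else alpha
  cc <- function(p) (1 + (k - 1) * p) / (1 - p)
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  1 - stats::pf(cc(p0) / cc(p1) * stats::qf(1 - a, df1, df2), df1, df2)
}

check_power_spec <- function(p0, p1, alpha, k) {
  if (!(p0 >= 0 && p0 < 1) || !(p1 > 0 && p1 < 1) || p1 <= p0)
    stop("need 0 <= p0 < p1 < 1", call. = FALSE)
  if (!(alpha > 0 && alpha < 0.5))
    stop("'alpha' must be in (0, 0.5)", call. = FALSE)
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  invisible(TRUE)
}

#' Sample size for an ICC reliability study
#'
#' Smallest number of subjects `n` such that the F-test of
#' `H0: ICC = p0` against the anticipated `ICC = p1` at level `alpha`
#' reaches the target power (see [icc_power()]). Power is monotone
#' increasing in `n`, so the minimum is found by direct search.
#'
#' @inheritParams icc_power
#' @param power Target power, in (0.5, 1) (default 0.9).
#' @param n_max Search cap.
#' @return The minimal `n` (integer).
#' @examples
#' icc_sample_size(p0 = 0.6, p1 = 0.9, alpha = 0.05, power = 0.8, k = 2)
#' @export
icc_sample_size <- function(p0, p1, alpha = 0.05, power = 0.9, k = 2,
                            two_sided = FALSE, n_max = 100000L) {
  check_power_spec(p0, p1, alpha, k)
  if (!(power > 0.5 && power < 1))
    stop("'power' must be in (0.5, 1)", call. = FALSE)
  lo <- k + 1
  hi <- lo
  while (icc_power(hi, p0, p1, alpha, k, two_sided) < power) {
    hi <- hi * 2
    if (hi > n_max) stop("no n <= n_max reaches the target power",
                         call. = FALSE)
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (icc_power(mid, p0, p1, alpha, k, two_sided) >= power) hi <- mid
    else lo <- mid + 1
  }
  as.integer(lo)
}

#' Power curve over a range of sample sizes
#'
#' @inheritParams icc_sample_size
#' @param n Vector of subject counts.
#' @return A data frame with columns `n` and `power`.
#' @export
icc_power_curve <- function(n, p0, p1, alpha = 0.05, k = 2,
                            two_sided = FALSE) {
  data.frame(n = n, power = icc_power(n, p0, p1, alpha, k, two_sided))
}

#' Designs consistent with a given sample size
#'
#' Exploratory report: scans a grid of (p0, p1) hypotheses and returns
#' those whose minimal sample size equals `n_target` at the given
#' power and level. Useful to see which anticipated-reliability
#' assumptions imply a published study size when the assumptions
#' themselves are not reported.
#'
#' @param n_target Sample size to reproduce.
#' @param p0_grid,p1_grid Hypothesis grids.
#' @inheritParams icc_sample_size
#' @return A data frame with columns `p0`, `p1`, `n`, restricted to
#'   `n == n_target`.
#' @export
icc_designs_for_n <- function(n_target, p0_grid = seq(0.4, 0.9, by = 0.05),
                              p1_grid = seq(0.5, 0.99, by = 0.01),
                              alpha = 0.05, power = 0.9, k = 2,
                              two_sided = FALSE) {
  grid <- expand.grid(p0 = p0_grid, p1 = p1_grid)
  grid <- grid[grid$p1 > grid$p0, , drop = FALSE]
  grid$n <- vapply(seq_len(nrow(grid)), function(i) {
    icc_sample_size(grid$p0[i], grid$p1[i], alpha, power, k, two_sided)
  }, integer(1))
  out <- grid[grid$n == n_target, , drop = FALSE]
  rownames(out) <- NULL
  out
}
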