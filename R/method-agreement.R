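#' Fit the full method-agreement analysis
#'
#' Central fit of the package: given time-matched double-sensor /
#' reference pairs that have passed the artifact filter, computes the
#' complete agreement battery — paired t-test, Bland-Altman bias, SD
#' and 95% limits of agreement with confidence intervals, the two-way
#' mixed-effects single-measure ICC with its F-method confidence
#' interval and Cicchetti class, and the percentage of pairs within the
#' a-priori acceptability threshold.
#'
#' Nothing is rounded internally; rounding happens only in the print
#' and serialisation methods (2 decimals for degrees C, ICC and t; p to
#' 2 significant figures), matching conventional reporting precision.
#'
#' @param object A `"paired_dataset"` (typically after
#'   [remove_artifacts()]; flagged pairs are excluded automatically),
#'   or a numeric vector of double-sensor core temperatures.
#' @param ref Reference temperatures, required when `object` is a bare
#'   numeric vector.
#' @param threshold A-priori acceptability threshold, degrees C
#'   (default 0.5).
#' @param alpha Two-sided significance / CI level complement
#'   (default 0.05).
#' @param icc_type `"consistency"` (default, ICC(3,1)) or
#'   `"agreement"`.
#' @param loa_mult Limits-of-agreement multiplier (default 1.96).
#' @param ... Passed between methods.
#' @return An object of class `"method_agreement"`: a list with
#'   components `n`, `bias`, `sd`, `bias_ci`, `loa_low`, `loa_high`,
#'   `loa_low_ci`, `loa_high_ci`, `t_stat`, `p_value`, `icc`, `icc_ci`,
#'   `icc_class`, `icc_type`, `pct_within`, `threshold`, `alpha`,
#'   `counts` (pair accounting when fitted from a filtered dataset) and
#'   `data` (mean/difference pairs for the Bland-Altman plot).
#' @examples
#' set.seed(2)
#' truth <- rnorm(200, 34.1, 1.5)
#' fit <- method_agreement(truth + rnorm(200, 0.02, 0.4),
#'                         truth + rnorm(200, 0, 0.4))
#' fit
#' coef(fit)
#' @export
method_agreement <- function(object, ...) UseMethod("method_agreement")

#' @rdname method_agreement
#' @export
method_agreement.paired_dataset <- function(object, threshold = 0.5,
                                            alpha = 0.05,
                                            icc_type = c("consistency",
                                                         "agreement"),
                                            loa_mult = 1.96, ...) {
  icc_type <- match.arg(icc_type)
  kept <- object[!object$artifact, , drop = FALSE]
  fit <- method_agreement.default(kept$ds_core_c, kept$ref_c,
                                  threshold = threshold, alpha = alpha,
                                  icc_type = icc_type, loa_mult = loa_mult)
  fit$counts <- attr(object, "counts")
  fit
}

#' @rdname method_agreement
#' @export
method_agreement.default <- function(object, ref, threshold = 0.5,
                                     alpha = 0.05,
                                     icc_type = c("consistency",
                                                  "agreement"),
                                     loa_mult = 1.96, ...) {
  icc_type <- match.arg(icc_type)
  ds <- as.numeric(object)
  ref <- as.numeric(ref)
  if (length(ds) != length(ref))
    stop("measurement vectors must have equal length", call. = FALSE)
  diffs <- ds - ref
  ba <- bland_altman(diffs, alpha = alpha, loa_mult = loa_mult)
  tt <- paired_t_test(diffs)
  ic <- icc_consistency(ds, ref, type = icc_type, alpha = alpha)
  structure(list(
    n = ba$n, bias = ba$bias, sd = ba$sd, bias_ci = ba$bias_ci,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    loa_low_ci = ba$loa_low_ci, loa_high_ci = ba$loa_high_ci,
    t_stat = tt$t_stat, p_value = tt$p_value,
    icc = ic$icc, icc_ci = ic$icc_ci, icc_class = classify_icc(ic$icc),
    icc_type = icc_type,
    pct_within = pct_within_threshold(diffs, threshold),
    threshold = threshold, alpha = alpha, loa_mult = loa_mult,
    counts = NULL,
    data = data.frame(mean_c = (ds + ref) / 2, diff_c = diffs)),
    class = "method_agreement")
}

fmt_ci <- function(ci, digits = 2) {
  sprintf("%.*f to %.*f", digits, ci[1], digits, ci[2])
}

#' @export
print.method_agreement <- function(x, ...) {
  cat("Method agreement: double sensor vs reference\n")
  if (!is.null(x$counts))
    cat(sprintf("  pairs: %d candidate, %d artifacts removed (%.1f%%), %d analysed\n",
                x$counts["total"], x$counts["artifacts"],
                100 * x$counts["artifacts"] / x$counts["total"], x$n))
  else
    cat(sprintf("  pairs analysed: %d\n", x$n))
  cat(sprintf("  bias %.2f C (%d%% CI %s), SD %.2f C\n",
              x$bias, round(100 * (1 - x$alpha)), fmt_ci(x$bias_ci), x$sd))
  cat(sprintf("  95%% LoA %.3f to %.3f C\n", x$loa_low, x$loa_high))
  cat(sprintf("  paired t = %.2f, p = %s (n = %d)\n",
              x$t_stat, format(signif(x$p_value, 2)), x$n))
  cat(sprintf("  ICC(%s, single) = %.2f (%d%% CI %s): %s\n",
              if (x$icc_type == "consistency") "C,1" else "A,1",
              x$icc, round(100 * (1 - x$alpha)), fmt_ci(x$icc_ci),
              x$icc_class))
  cat(sprintf("  %.0f%% of pairs within +/- %.1f C\n",
              x$pct_within, x$threshold))
  invisible(x)
}

#' @export
summary.method_agreement <- function(object, ...) {
  print(object)
  cat(sprintf("  LoA CIs: lower %s; upper %s\n",
              fmt_ci(object$loa_low_ci, 3), fmt_ci(object$loa_high_ci, 3)))
  invisible(object)
}

#' @export
coef.method_agreement <- function(object, ...) {
  c(bias = object$bias, sd = object$sd, loa_low = object$loa_low,
    loa_high = object$loa_high, icc = object$icc,
    pct_within = object$pct_within)
}

#' @export
residuals.method_agreement <- function(object, ...) {
  object$data$diff_c - object$bias
}

#' Bland-Altman plot of a fitted agreement analysis
#'
#' Scatter of per-pair differences against per-pair means with the bias
#' line and the two limits of agreement.
#'
#' @param x A `"method_agreement"` fit.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.method_agreement <- function(x, ...) {
  graphics::plot(x$data$mean_c, x$data$diff_c,
                 xlab = "Mean of methods (°C)",
                 ylab = "Difference, sensor − reference (°C)",
                 main = "Bland-Altman plot", ...)
  graphics::abline(h = x$bias, col = "blue")
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "darkgreen",
                   lty = 2)
  invisible(x)
}

#' Serialise / restore an agreement report
#'
#' `write_agreement_report()` writes the numeric report as JSON at full
#' precision (plus a plain-text rendering alongside when
#' `text = TRUE`); `read_agreement_report()` restores it. Values
#' round-trip exactly; rounding is a display concern only.
#'
#' @param x A `"method_agreement"` fit.
#' @param path Output JSON path.
#' @param text Also write `<path>.txt` with the printed rendering.
#' @return `write_agreement_report()` returns `path` invisibly;
#'   `read_agreement_report()` returns a `"method_agreement"` object
#'   (without the per-pair plot data).
#' @export
write_agreement_report <- function(x, path, text = FALSE) {
  stopifnot(inherits(x, "method_agreement"))
  fields <- x[setdiff(names(x), "data")]
  fields$counts <- if (is.null(fields$counts)) NULL else
    as.list(fields$counts)
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (text) writeLines(utils::capture.output(print(x)),
                       paste0(path, ".txt"))
  invisible(path)
}

#' @rdname write_agreement_report
#' @export
read_agreement_report <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(fields$counts)) fields$counts <- unlist(fields$counts)
  fields$data <- NULL
  structure(fields, class = "method_agreement")
}

#' Export Bland-Altman plot data
#'
#' Writes the per-pair (mean, difference) table plus the three
#' reference lines (bias and the two limits of agreement) as CSV for
#' external plotting.
#'
#' @param x A `"method_agreement"` fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ba_plot_data <- function(x, path) {
  stopifnot(inherits(x, "method_agreement"))
  utils::write.csv(x$data, path, row.names = FALSE)
  lines_path <- sub("(\\.[^.]+)?$", "_lines\\1", path)
  utils::write.csv(data.frame(line = c("bias", "loa_low", "loa_high"),
                              value = c(x$bias, x$loa_low, x$loa_high)),
                   lines_path, row.names = FALSE)
  invisible(path)
}
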