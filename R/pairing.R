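#' Time-match the double-sensor stream to the reference stream
#'
#' Reduces the 1 Hz double-sensor stream to one candidate pair per
#' reference tick. For each tick, the double-sensor core temperature is
#' the mean of [compute_core_temp()] over all samples in the centred
#' window `[t - window_s/2, t + window_s/2]` (default 60 s: robust to
#' 1 Hz timing jitter while preserving the 30-min cadence). A
#' `"nearest"` mode instead takes the single closest sample within the
#' half-window, for sensitivity analysis. Ticks whose window contains
#' no double-sensor sample (logger dropouts, span mismatch) are skipped
#' and counted, not imputed.
#'
#' The difference column is always double-sensor minus reference.
#'
#' @param ds A [dual_sensor_stream()].
#' @param ref A [reference_stream()].
#' @param model A [heat_flux_model()] converting `(th1, th2)` to core
#'   temperature.
#' @param window_s Matching window width, seconds (> 0).
#' @param method `"window_mean"` (default) or `"nearest"`.
#' @param patient Optional patient identifier carried into the output.
#' @return A data frame of class `"paired_dataset"` with columns `t_s`,
#'   `ds_core_c`, `ref_c`, `diff_c` (`ds_core_c - ref_c`), `artifact`
#'   (all `FALSE` until [remove_artifacts()] runs) and, if supplied,
#'   `patient`; attribute `skipped_ticks` counts unmatched reference
#'   ticks. If the streams do not overlap a warning is issued and an
#'   empty dataset returned.
#' @export
pair_streams <- function(ds, ref, model = heat_flux_model(), window_s = 60,
                         method = c("window_mean", "nearest"),
                         patient = NULL) {
  stopifnot(inherits(ds, "dual_sensor_stream"),
            inherits(ref, "reference_stream"))
  if (!(window_s > 0)) stop("'window_s' must be > 0", call. = FALSE)
  method <- match.arg(method)
  if (nrow(ds) == 0L || nrow(ref) == 0L)
    stop("both streams must be non-empty", call. = FALSE)

  core <- compute_core_temp(ds$th1_c, ds$th2_c, model)
  half <- window_s / 2
  # window [tick - half, tick + half], both ends inclusive
  lo <- findInterval(ref$t_s - half, ds$t_s, left.open = TRUE) + 1L
  hi <- findInterval(ref$t_s + half, ds$t_s)
  n_in <- pmax(hi - lo + 1L, 0L)

  matched <- n_in > 0L
  if (!any(matched)) {
    warning("streams do not overlap: no reference tick matched",
            call. = FALSE)
  }

  if (method == "window_mean") {
    cs <- c(0, cumsum(core))
    ds_core <- ifelse(matched, (cs[hi + 1L] - cs[pmax(lo, 1L)]) / n_in,
                      NA_real_)
  } else {
    ds_core <- rep(NA_real_, nrow(ref))
    for (j in which(matched)) {
      idx <- lo[j]:hi[j]
      ds_core[j] <- core[idx[which.min(abs(ds$t_s[idx] - ref$t_s[j]))]]
    }
  }

  out <- data.frame(t_s = ref$t_s[matched], ds_core_c = ds_core[matched],
                    ref_c = ref$temp_c[matched])
  out$diff_c <- out$ds_core_c - out$ref_c
  out$artifact <- rep(FALSE, nrow(out))
  if (!is.null(patient)) out$patient <- rep(patient, nrow(out))
  structure(out, skipped_ticks = sum(!matched), filtered = FALSE,
            class = c("paired_dataset", "data.frame"))
}

#' Pair every patient of a simulated cohort
#'
#' Convenience wrapper running [pair_streams()] on each patient bundle
#' and pooling the results with a `patient` column.
#'
#' @param cohort_data A `"ttm_cohort"` list from [simulate_cohort()].
#' @inheritParams pair_streams
#' @return A pooled `"paired_dataset"`.
#' @export
pair_cohort <- function(cohort_data, model = heat_flux_model(),
                        window_s = 60,
                        method = c("window_mean", "nearest")) {
  stopifnot(inherits(cohort_data, "ttm_cohort"))
  method <- match.arg(method)
  parts <- lapply(seq_along(cohort_data), function(i) {
    pair_streams(cohort_data[[i]]$ds, cohort_data[[i]]$ref, model = model,
                 window_s = window_s, method = method, patient = i)
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  structure(out,
            skipped_ticks = sum(vapply(parts, attr, 0L, "skipped_ticks")),
            filtered = FALSE,
            class = c("paired_dataset", "data.frame"))
}

#' Flag artifact pairs by the pooled 2-SD rule
#'
#' Computes the mean `m` and sample SD `s` of the differences once, in
#' a single pass over the pooled input, and flags every pair whose
#' difference deviates from `m` by more than `2 s`. The rule is applied
#' exactly once per analysis (re-running it on the retained pairs would
#' remove more); the pipeline enforces single application by structure.
#'
#' Variants for sensitivity analysis: `center = "zero"` measures the
#' deviation from 0 instead of from the mean difference, and
#' `by_patient = TRUE` computes `m` and `s` within each patient rather
#' than pooled over the cohort.
#'
#' @param data A `"paired_dataset"` from [pair_streams()] /
#'   [pair_cohort()] with at least 3 pairs.
#' @param center `"mean"` (default) or `"zero"`.
#' @param by_patient Compute the corridor per patient (requires a
#'   `patient` column).
#' @return The dataset with the `artifact` column set and attribute
#'   `counts` — a named vector `c(total, artifacts, retained)` with
#'   `retained = total - artifacts`.
#' @seealso [retained()] to extract the non-flagged pairs.
#' @export
remove_artifacts <- function(data, center = c("mean", "zero"),
                             by_patient = FALSE) {
  stopifnot(inherits(data, "paired_dataset"))
  center <- match.arg(center)
  if (nrow(data) < 3L)
    stop("artifact filter undefined for fewer than 3 pairs", call. = FALSE)
  flag_one <- function(d) {
    m <- if (center == "mean") mean(d) else 0
    s <- stats::sd(d)
    abs(d - m) > 2 * s
  }
  if (by_patient) {
    if (is.null(data$patient))
      stop("'by_patient = TRUE' requires a 'patient' column", call. = FALSE)
    flags <- stats::ave(data$diff_c, data$patient,
                        FUN = function(d) as.numeric(flag_one(d))) > 0
  } else {
    flags <- flag_one(data$diff_c)
  }
  data$artifact <- flags
  attr(data, "counts") <- c(total = nrow(data),
                            artifacts = sum(flags),
                            retained = nrow(data) - sum(flags))
  attr(data, "filtered") <- TRUE
  data
}

#' Retained (non-artifact) pairs
#' @param data A filtered `"paired_dataset"`.
#' @return The subset of rows with `artifact == FALSE`, still a
#'   `"paired_dataset"`.
#' @export
retained <- function(data) {
  stopifnot(inherits(data, "paired_dataset"))
  out <- data[!data$artifact, , drop = FALSE]
  attr(out, "counts") <- attr(data, "counts")
  attr(out, "filtered") <- attr(data, "filtered")
  attr(out, "skipped_ticks") <- attr(data, "skipped_ticks")
  class(out) <- class(data)
  out
}

#' @export
print.paired_dataset <- function(x, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("Paired dataset: %d pairs", nrow(x)))
  if (!is.null(x$patient))
    cat(sprintf(" from %d patients", length(unique(x$patient))))
  if (isTRUE(attr(x, "filtered")) && !is.null(cts)) {
    cat(sprintf("\n  artifact filter: %d flagged of %d (%.1f%%), %d retained",
                cts["artifacts"], cts["total"],
                100 * cts["artifacts"] / cts["total"], cts["retained"]))
  }
  sk <- attr(x, "skipped_ticks")
  if (!is.null(sk) && sk > 0)
    cat(sprintf("\n  %d reference ticks had no double-sensor data", sk))
  cat("\n")
  invisible(x)
}
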