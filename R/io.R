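#' Read a temperature stream file
#'
#' Streams are plain comma-separated text with a header line:
#' double-sensor files carry `t_s, th1_c, th2_c` (optionally
#' `ambient_c`), reference files `t_s, temp_c`. Timestamps are seconds
#' from stream start with a decimal point; missing values are empty
#' fields. Malformed rows and non-monotone timestamps are reported with
#' their line number; a header-only file is an empty-stream error,
#' distinct from a parse error.
#'
#' @param path File path.
#' @param kind `"ds"` (double sensor) or `"ref"` (reference).
#' @param corridor Plausibility corridor passed to
#'   [dual_sensor_stream()].
#' @return A [dual_sensor_stream()] or [reference_stream()].
#' @export
read_stream <- function(path, kind = c("ds", "ref"), corridor = c(15, 45)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  need <- if (kind == "ds") c("t_s", "th1_c", "th2_c") else c("t_s", "temp_c")
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop(sprintf("parse error in '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE),
    warning = function(w) stop(sprintf("parse error in '%s': %s", path,
                                       conditionMessage(w)), call. = FALSE))
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' lacks required columns %s for kind '%s'", path,
                 paste(setdiff(need, names(df)), collapse = ", "), kind),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("empty stream: '%s' has a header but no data rows", path),
         call. = FALSE)
  if (nrow(df) > 1L && any(diff(df$t_s) <= 0)) {
    bad <- which(diff(df$t_s) <= 0)[1L] + 1L
    stop(sprintf("timestamps not strictly increasing at line %d of '%s'",
                 bad + 1L, path), call. = FALSE)   # +1 for the header line
  }
  message(sprintf("read %d rows from '%s' (%s stream)", nrow(df), path, kind))
  if (kind == "ds")
    dual_sensor_stream(df$t_s, df$th1_c, df$th2_c, ambient_c = df$ambient_c,
                       corridor = corridor)
  else
    reference_stream(df$t_s, df$temp_c)
}

#' Write a temperature stream file
#'
#' Inverse of [read_stream()]: comma-separated, header line, decimal
#' point, UTF-8. The `suspect` quality flag of a double-sensor stream
#' is derived data and is not written.
#'
#' @param stream A [dual_sensor_stream()] or [reference_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  df <- as.data.frame(stream)
  df$suspect <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' Collects every stage's parameters into one validated object. All
#' validation happens here, before any stage runs; [run_pipeline()]
#' refuses anything else. `input` switches the pipeline between
#' simulation (default) and reading existing stream files: a list of
#' `list(ds = <path>, ref = <path>)` pairs, one per patient.
#'
#' @param model A [heat_flux_model()] or bare Ks/Kg ratio.
#' @param protocol A [ttm_protocol()].
#' @param params A [patient_params()].
#' @param cohort A [cohort_config()].
#' @param window_s Pairing window, seconds.
#' @param pairing_method `"window_mean"` or `"nearest"`.
#' @param artifact_center `"mean"` or `"zero"`.
#' @param artifact_by_patient Pool the 2-SD corridor per patient.
#' @param icc_type `"consistency"` or `"agreement"`.
#' @param threshold A-priori acceptability threshold, degrees C.
#' @param alpha Significance / CI level complement.
#' @param input `NULL` to simulate, or a list of per-patient
#'   `list(ds=, ref=)` file paths.
#' @param out_dir Optional output directory; when set, the paired
#'   table, the report (JSON and text), the Bland-Altman plot data and
#'   the effective configuration are written there.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(model = heat_flux_model(), protocol = ttm_protocol(),
                       params = patient_params(),
                       cohort = cohort_config(25),
                       window_s = 60,
                       pairing_method = c("window_mean", "nearest"),
                       artifact_center = c("mean", "zero"),
                       artifact_by_patient = FALSE,
                       icc_type = c("consistency", "agreement"),
                       threshold = 0.5, alpha = 0.05,
                       input = NULL, out_dir = NULL) {
  model <- as_heat_flux_model(model)
  stopifnot(inherits(protocol, "ttm_protocol"),
            inherits(params, "patient_params"),
            inherits(cohort, "cohort_config"))
  if (!(window_s > 0)) stop("'window_s' must be > 0", call. = FALSE)
  if (!(threshold > 0)) stop("'threshold' must be > 0", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)",
                                      call. = FALSE)
  if (!is.null(input) &&
      !all(vapply(input, function(p) is.list(p) &&
                    all(c("ds", "ref") %in% names(p)), TRUE)))
    stop("'input' must be a list of list(ds=, ref=) path pairs",
         call. = FALSE)
  structure(list(model = model, protocol = protocol, params = params,
                 cohort = cohort, window_s = window_s,
                 pairing_method = match.arg(pairing_method),
                 artifact_center = match.arg(artifact_center),
                 artifact_by_patient = artifact_by_patient,
                 icc_type = match.arg(icc_type), threshold = threshold,
                 alpha = alpha, input = input, out_dir = out_dir),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a structured YAML file whose top-level blocks mirror the
#' [run_config()] arguments (`model`, `protocol`, `params`, `cohort`,
#' `pairing`, `analysis`, `input`, `out_dir`); omitted entries keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A validated `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$model)) args$model <- do.call(heat_flux_model, y$model)
  if (!is.null(y$protocol)) args$protocol <- do.call(ttm_protocol, y$protocol)
  if (!is.null(y$params)) {
    if (!is.null(y$params$dropout_segments))
      y$params$dropout_segments <- lapply(y$params$dropout_segments, unlist)
    args$params <- do.call(patient_params, y$params)
  }
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  for (nm in c("window_s", "pairing_method", "artifact_center",
               "artifact_by_patient", "icc_type", "threshold", "alpha",
               "input", "out_dir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(run_config, args)
}

# flatten the effective config for echoing into the output directory
config_as_list <- function(config) {
  list(model = unclass(config$model), protocol = unclass(config$protocol),
       params = unclass(config$params), cohort = unclass(config$cohort),
       window_s = config$window_s, pairing_method = config$pairing_method,
       artifact_center = config$artifact_center,
       artifact_by_patient = config$artifact_by_patient,
       icc_type = config$icc_type, threshold = config$threshold,
       alpha = config$alpha,
       input = config$input, out_dir = config$out_dir)
}

#' Run the full validation pipeline
#'
#' Simulate (or read) the per-patient streams, derive core temperatures
#' from the raw sensor channels, time-match against the reference,
#' apply the pooled 2-SD artifact filter once, and fit
#' [method_agreement()] on the retained pairs. Deterministic given the
#' cohort seed; stage counts (stream samples, candidate pairs,
#' artifacts, retained) are logged via `message()` and returned, so a
#' run's accounting can be audited.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return A list of class `"pipeline_result"`: `report` (the
#'   `"method_agreement"` fit), `paired` (the flagged paired dataset),
#'   `counts` (named stage counts) and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (is.null(config$input)) {
    cohort_data <- stage("simulate",
                         simulate_cohort(config$cohort, config$protocol,
                                         config$params, config$model))
  } else {
    cohort_data <- stage("read", {
      bundles <- lapply(config$input, function(p) {
        list(ds = read_stream(p$ds, "ds"), ref = read_stream(p$ref, "ref"))
      })
      class(bundles) <- "ttm_cohort"
      bundles
    })
  }
  n_ds <- sum(vapply(cohort_data, function(b) nrow(b$ds), 0L))
  n_ref <- sum(vapply(cohort_data, function(b) nrow(b$ref), 0L))
  message(sprintf("streams: %d double-sensor samples, %d reference samples",
                  n_ds, n_ref))

  paired <- stage("pair",
                  pair_cohort(cohort_data, model = config$model,
                              window_s = config$window_s,
                              method = config$pairing_method))
  message(sprintf("pairing: %d candidate pairs (%d ticks unmatched)",
                  nrow(paired), attr(paired, "skipped_ticks")))

  flagged <- stage("filter",
                   remove_artifacts(paired, center = config$artifact_center,
                                    by_patient = config$artifact_by_patient))
  cts <- attr(flagged, "counts")
  message(sprintf("artifact filter: %d flagged of %d (%.1f%%), %d retained",
                  cts["artifacts"], cts["total"],
                  100 * cts["artifacts"] / cts["total"], cts["retained"]))

  report <- stage("agreement",
                  method_agreement(flagged, threshold = config$threshold,
                                   alpha = config$alpha,
                                   icc_type = config$icc_type))

  counts <- c(ds_samples = n_ds, ref_samples = n_ref,
              skipped_ticks = attr(paired, "skipped_ticks"),
              candidate_pairs = unname(cts["total"]),
              artifacts = unname(cts["artifacts"]),
              retained = unname(cts["retained"]))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(flagged),
                     file.path(config$out_dir, "paired.csv"),
                     row.names = FALSE)
    write_agreement_report(report, file.path(config$out_dir, "report.json"),
                           text = TRUE)
    write_ba_plot_data(report, file.path(config$out_dir, "ba_plot.csv"))
    yaml::write_yaml(config_as_list(config),
                     file.path(config$out_dir, "config.yaml"))
  }

  structure(list(report = report, paired = flagged, counts = counts,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("TTM double-sensor validation pipeline\n")
  cat(sprintf("  %d double-sensor and %d reference samples\n",
              x$counts["ds_samples"], x$counts["ref_samples"]))
  cat(sprintf("  %d candidate pairs, %d artifacts removed, %d retained\n",
              x$counts["candidate_pairs"], x$counts["artifacts"],
              x$counts["retained"]))
  print(x$report)
  invisible(x)
}
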