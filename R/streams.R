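#' Temperature stream containers
#'
#' Light data-frame wrappers for the two logger outputs: the 1 Hz
#' double-sensor stream (`t_s`, `th1_c`, `th2_c`, optional `ambient_c`)
#' and the sparse esophageal reference stream (`t_s`, `temp_c`).
#' Timestamps are seconds since stream start and must be non-negative
#' and strictly increasing. Sensor readings outside the plausibility
#' corridor (default 15-45 degrees C, catching detached sensors) are
#' flagged in a `suspect` column, never dropped: the pooled 2-SD
#' artifact filter remains the sole exclusion step in the pipeline.
#'
#' @param t_s Timestamps, seconds; non-negative, strictly increasing.
#' @param th1_c,th2_c Skin-side and environment-side sensor readings,
#'   degrees C.
#' @param ambient_c Optional ambient temperature, degrees C.
#' @param corridor Plausibility corridor `c(low, high)` for flagging.
#' @return A data frame of class `"dual_sensor_stream"` or
#'   `"reference_stream"`.
#' @export
dual_sensor_stream <- function(t_s, th1_c, th2_c, ambient_c = NULL,
                               corridor = c(15, 45)) {
  check_timestamps(t_s)
  stopifnot(length(th1_c) == length(t_s), length(th2_c) == length(t_s))
  suspect <- !is.finite(th1_c) | !is.finite(th2_c) |
    th1_c < corridor[1] | th1_c > corridor[2] |
    th2_c < corridor[1] | th2_c > corridor[2]
  out <- data.frame(t_s = as.numeric(t_s), th1_c = as.numeric(th1_c),
                    th2_c = as.numeric(th2_c))
  if (!is.null(ambient_c)) out$ambient_c <- as.numeric(ambient_c)
  out$suspect <- suspect
  class(out) <- c("dual_sensor_stream", "data.frame")
  out
}

#' @rdname dual_sensor_stream
#' @param temp_c Reference (esophageal) temperature, degrees C.
#' @export
reference_stream <- function(t_s, temp_c) {
  check_timestamps(t_s)
  stopifnot(length(temp_c) == length(t_s))
  out <- data.frame(t_s = as.numeric(t_s), temp_c = as.numeric(temp_c))
  class(out) <- c("reference_stream", "data.frame")
  out
}

check_timestamps <- function(t_s) {
  if (length(t_s) == 0L) return(invisible(TRUE))
  if (any(!is.finite(t_s)) || any(t_s < 0))
    stop("timestamps must be finite and non-negative", call. = FALSE)
  if (length(t_s) > 1L && any(diff(t_s) <= 0)) {
    bad <- which(diff(t_s) <= 0)[1L] + 1L
    stop(sprintf("timestamps not strictly increasing at row %d", bad),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.dual_sensor_stream <- function(x, ...) {
  cat(sprintf("Double-sensor stream: %d samples over %.2f h, %d suspect\n",
              nrow(x), if (nrow(x)) diff(range(x$t_s)) / 3600 else 0,
              sum(x$suspect)))
  invisible(x)
}

#' @export
print.reference_stream <- function(x, ...) {
  cat(sprintf("Reference stream: %d samples over %.2f h\n",
              nrow(x), if (nrow(x)) diff(range(x$t_s)) / 3600 else 0))
  invisible(x)
}
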