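#' Targeted temperature management protocol
#'
#' Parameterises the clinical TTM protocol the simulator follows:
#' linear induction cooling from `start_temp` to `target_temp`, a
#' maintenance plateau, controlled rewarming at `rewarm_rate` up to
#' `post_target`, and a normothermia hold to intercept rebound fever.
#'
#' The protocol itself specifies the 33 degree C target, the 24 h
#' maintenance, the 0.25 degree C/h rewarming and the 37 degree C /
#' 24 h post-hold. Induction rate and admission temperature are not
#' part of the published protocol; the defaults (1.5 degree C/h from
#' 35.5 degree C) reflect the mild spontaneous hypothermia typical of
#' post-arrest patients and are configurable.
#'
#' @param start_temp Core temperature at protocol start, degrees C.
#' @param induction_rate Cooling rate during induction, degrees C/h (> 0).
#' @param target_temp Hypothermia target, degrees C.
#' @param maintenance_h Duration of the maintenance plateau, hours.
#' @param rewarm_rate Rewarming rate, degrees C/h (> 0).
#' @param post_target Post-rewarming target, degrees C (> `target_temp`).
#' @param post_hold_h Duration of the normothermia hold, hours.
#' @return An object of class `"ttm_protocol"`.
#' @examples
#' p <- ttm_protocol()
#' protocol_duration_h(p) # induction + 24 + 16 + 24 hours
#' @export
ttm_protocol <- function(start_temp = 35.5, induction_rate = 1.5,
                         target_temp = 33, maintenance_h = 24,
                         rewarm_rate = 0.25, post_target = 37,
                         post_hold_h = 24) {
  stopifnot(is.finite(start_temp), is.finite(target_temp),
            is.finite(post_target))
  if (!(induction_rate > 0) || !(rewarm_rate > 0))
    stop("induction_rate and rewarm_rate must be > 0", call. = FALSE)
  if (maintenance_h < 0 || post_hold_h < 0)
    stop("phase durations must be >= 0", call. = FALSE)
  if (!(target_temp < post_target))
    stop("target_temp must be below post_target", call. = FALSE)
  if (start_temp < target_temp)
    stop("start_temp must be at or above target_temp", call. = FALSE)
  structure(list(start_temp = start_temp, induction_rate = induction_rate,
                 target_temp = target_temp, maintenance_h = maintenance_h,
                 rewarm_rate = rewarm_rate, post_target = post_target,
                 post_hold_h = post_hold_h),
            class = "ttm_protocol")
}

#' @export
print.ttm_protocol <- function(x, ...) {
  cat("TTM protocol:\n")
  cat(sprintf("  induction : %.2f -> %.2f C at %.2f C/h (%.2f h)\n",
              x$start_temp, x$target_temp, x$induction_rate,
              (x$start_temp - x$target_temp) / x$induction_rate))
  cat(sprintf("  maintain  : %.2f C for %g h\n", x$target_temp,
              x$maintenance_h))
  cat(sprintf("  rewarm    : %.2f C/h to %.2f C (%.2f h)\n", x$rewarm_rate,
              x$post_target, (x$post_target - x$target_temp) / x$rewarm_rate))
  cat(sprintf("  post hold : %.2f C for %g h\n", x$post_target, x$post_hold_h))
  invisible(x)
}

# phase boundaries in hours since protocol start
protocol_phases_h <- function(protocol) {
  ind <- (protocol$start_temp - protocol$target_temp) / protocol$induction_rate
  rew <- (protocol$post_target - protocol$target_temp) / protocol$rewarm_rate
  c(induction_end = ind,
    maintenance_end = ind + protocol$maintenance_h,
    rewarm_end = ind + protocol$maintenance_h + rew,
    post_end = ind + protocol$maintenance_h + rew + protocol$post_hold_h)
}

#' Total protocol duration in hours
#' @param protocol A [ttm_protocol()].
#' @return Hours from start to the end of the normothermia hold.
#' @export
protocol_duration_h <- function(protocol) {
  unname(protocol_phases_h(protocol)["post_end"])
}

# noiseless piecewise-linear core temperature at times t (hours)
protocol_core_at_h <- function(protocol, t_h) {
  ph <- protocol_phases_h(protocol)
  core <- numeric(length(t_h))
  ind <- t_h < ph["induction_end"]
  core[ind] <- protocol$start_temp - protocol$induction_rate * t_h[ind]
  mnt <- t_h >= ph["induction_end"] & t_h < ph["maintenance_end"]
  core[mnt] <- protocol$target_temp
  rew <- t_h >= ph["maintenance_end"] & t_h < ph["rewarm_end"]
  core[rew] <- protocol$target_temp +
    protocol$rewarm_rate * (t_h[rew] - ph["maintenance_end"])
  post <- t_h >= ph["rewarm_end"]
  core[post] <- protocol$post_target
  core
}

#' Generate a protocol core-temperature trajectory
#'
#' Evaluates the noiseless piecewise-linear protocol trajectory on a
#' regular time grid and optionally superimposes stationary AR(1)
#' physiological jitter. During maintenance the noiseless trajectory is
#' exactly `target_temp`; during rewarming its slope is exactly
#' `rewarm_rate`; once `post_target` is reached it holds there.
#'
#' The jitter is a stationary first-order autoregression with marginal
#' standard deviation `jitter_sd` and per-step autocorrelation
#' `jitter_ar` (applied per grid step); it prevents a perfectly
#' deterministic plateau. Set `jitter_sd = 0` for analytic tests.
#'
#' @param protocol A [ttm_protocol()].
#' @param duration_h Length of the trajectory, hours; must cover at
#'   least induction plus maintenance.
#' @param step_s Grid step in seconds (> 0).
#' @param jitter_sd Marginal SD of the AR(1) jitter, degrees C.
#' @param jitter_ar AR(1) coefficient per step, in \[0, 1).
#' @return A data frame with columns `t_s` (seconds since start) and
#'   `core_c` (degrees C), the grid including `t = 0` and the endpoint.
#' @examples
#' tr <- protocol_trajectory(ttm_protocol(), duration_h = 48, step_s = 60,
#'                           jitter_sd = 0)
#' range(tr$core_c)
#' @export
protocol_trajectory <- function(protocol, duration_h = 48, step_s = 1,
                                jitter_sd = 0.05, jitter_ar = 0.99) {
  stopifnot(inherits(protocol, "ttm_protocol"))
  if (!(step_s > 0)) stop("'step_s' must be > 0", call. = FALSE)
  ph <- protocol_phases_h(protocol)
  if (duration_h < ph["maintenance_end"])
    stop("'duration_h' must cover at least induction plus maintenance",
         call. = FALSE)
  if (jitter_sd < 0 || jitter_ar < 0 || jitter_ar >= 1)
    stop("invalid jitter parameters", call. = FALSE)
  t_s <- seq(0, duration_h * 3600, by = step_s)
  core <- protocol_core_at_h(protocol, t_s / 3600)
  if (jitter_sd > 0) core <- core + ar1_noise(length(core), jitter_sd,
                                              jitter_ar)
  data.frame(t_s = t_s, core_c = core)
}

# stationary AR(1) series, marginal sd `sd`, lag-1 coefficient `phi`
ar1_noise <- function(n, sd, phi) {
  if (n == 0L) return(numeric(0))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}
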