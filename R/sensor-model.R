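#' Heat-flux double-sensor model
#'
#' The double sensor stacks two thermistors separated by an insulating
#' layer: the inner one (`Th1`) reads the skin, the outer one (`Th2`)
#' reads the temperature after the heat flux through the insulation.
#' Under the steady-state assumption that the flux through the
#' insulation equals the flux through the underlying tissue, core body
#' temperature is a linear function of the two readings,
#' \deqn{T_{core} = T_{h1} + \frac{K_s}{K_g}(T_{h1} - T_{h2}),}
#' where \eqn{K_s} and \eqn{K_g} are the heat-transfer coefficients of
#' the insulation and of human tissue. The model is fully described by
#' the single dimensionless ratio \eqn{K_s/K_g}.
#'
#' The device manufacturer does not publish numeric coefficients, so the
#' ratio is a configuration parameter (default 0.5). All downstream
#' agreement statistics are invariant to its value when the simulator's
#' forward model and the analysis use the same ratio, which the test
#' suite asserts.
#'
#' @param ks_over_kg Ratio of insulation to tissue heat-transfer
#'   coefficients; a strictly positive, finite number.
#' @return An object of class `"heat_flux_model"`.
#' @examples
#' m <- heat_flux_model(0.5)
#' compute_core_temp(35, 33, m)
#' @export
heat_flux_model <- function(ks_over_kg = 0.5) {
  if (!is.numeric(ks_over_kg) || length(ks_over_kg) != 1L ||
      !is.finite(ks_over_kg) || ks_over_kg <= 0) {
    stop("'ks_over_kg' must be a single finite number > 0", call. = FALSE)
  }
  structure(list(ks_over_kg = as.numeric(ks_over_kg)),
            class = "heat_flux_model")
}

#' @export
print.heat_flux_model <- function(x, ...) {
  cat("Heat-flux double-sensor model: Ks/Kg =", format(x$ks_over_kg), "\n")
  invisible(x)
}

# allow_zero: the forward formula is well defined at Ks/Kg = 0 (it
# degenerates to the skin reading) even though the model type and the
# inverse require a strictly positive ratio
as_heat_flux_model <- function(model, allow_zero = FALSE) {
  if (inherits(model, "heat_flux_model")) return(model)
  if (is.numeric(model) && length(model) == 1L && is.finite(model)) {
    if (model > 0) return(heat_flux_model(model))
    if (allow_zero && model == 0)
      return(structure(list(ks_over_kg = 0), class = "heat_flux_model"))
  }
  stop("'model' must be a heat_flux_model or a single Ks/Kg ratio > 0",
       call. = FALSE)
}

#' Core temperature from the two sensor readings
#'
#' Evaluates the steady-state heat-flux formula
#' `Tcore = Th1 + Ks/Kg * (Th1 - Th2)`. Vectorised over `th1`/`th2`;
#' the result is an exact linear function of the inputs, with no
#' clamping or smoothing.
#'
#' @param th1 Skin-side sensor temperature(s), degrees C.
#' @param th2 Environment-side sensor temperature(s), degrees C.
#' @param model A [heat_flux_model()] (or a bare Ks/Kg ratio).
#' @return Core temperature(s) in degrees C.
#' @examples
#' compute_core_temp(35, 33, heat_flux_model(0.75)) # 36.5
#' @seealso [forward_skin_temps()] for the algebraic inverse.
#' @export
compute_core_temp <- function(th1, th2, model = heat_flux_model()) {
  model <- as_heat_flux_model(model, allow_zero = TRUE)
  if (!is.numeric(th1) || any(!is.finite(th1)))
    stop("non-finite value in 'th1'", call. = FALSE)
  if (!is.numeric(th2) || any(!is.finite(th2)))
    stop("non-finite value in 'th2'", call. = FALSE)
  th1 + model$ks_over_kg * (th1 - th2)
}

#' Sensor readings that encode a given core temperature
#'
#' Algebraic inverse of [compute_core_temp()], used by the simulator to
#' turn a true core trajectory into the pair of raw sensor channels:
#' `th1 = tcore - skin_offset` and `th2 = th1 - skin_offset / (Ks/Kg)`,
#' so that the forward formula recovers `tcore` exactly.
#'
#' @param tcore Core temperature(s), degrees C.
#' @param skin_offset Core-to-skin gradient(s), degrees C; must be
#'   non-negative (core at least as warm as skin in this regime).
#' @param model A [heat_flux_model()] (or a bare Ks/Kg ratio).
#' @return A list with numeric components `th1` and `th2`.
#' @examples
#' s <- forward_skin_temps(33, 1, heat_flux_model(0.5)) # th1 = 32, th2 = 30
#' compute_core_temp(s$th1, s$th2, heat_flux_model(0.5)) # 33
#' @export
forward_skin_temps <- function(tcore, skin_offset, model = heat_flux_model()) {
  model <- as_heat_flux_model(model, allow_zero = TRUE)
  if (model$ks_over_kg == 0)
    stop("inverse undefined for ks_over_kg = 0", call. = FALSE)
  if (!is.numeric(tcore) || any(!is.finite(tcore)))
    stop("non-finite value in 'tcore'", call. = FALSE)
  if (!is.numeric(skin_offset) || any(!is.finite(skin_offset)) ||
      any(skin_offset < 0))
    stop("'skin_offset' must be finite and >= 0", call. = FALSE)
  th1 <- tcore - skin_offset
  th2 <- th1 - skin_offset / model$ks_over_kg
  list(th1 = th1, th2 = th2)
}
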