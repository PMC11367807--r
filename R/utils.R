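# Shared constants, unit conversions and classed error helper.

#' Universal gas constant
#'
#' Fixed at 8.314 J/(mol K); used by every Arrhenius computation in the
#' package.
#'
#' @format Numeric scalar, J/(mol K).
#' @export
R_GAS <- 8.314

# classed condition so callers (and the CLI) can dispatch on error type
rheo_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rheoprony_error")))
}

#' Temperature unit conversions
#'
#' Temperatures are Kelvin inside all model mathematics and degrees Celsius
#' at every file and user-facing boundary (rheometer reports print Celsius).
#'
#' @param x Numeric vector of temperatures.
#' @return Numeric vector in the other unit.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' Frequency unit conversions
#'
#' Rheometers report cyclic frequency in Hz; all model mathematics uses
#' angular frequency omega = 2 pi f (rad/s). Conversion happens exactly once,
#' at the I/O boundary.
#'
#' @param f Cyclic frequency, Hz.
#' @param omega Angular frequency, rad/s.
#' @return Converted frequency vector.
#' @export
hz_to_rad <- function(f) 2 * pi * f

#' @rdname hz_to_rad
#' @export
rad_to_hz <- function(omega) omega / (2 * pi)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rheo_abort(sprintf("'%s' must be a finite numeric scalar", name),
               "rheo_domain_error")
  }
  invisible(x)
}
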