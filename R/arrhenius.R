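# Arrhenius time-temperature shift.

#' Arrhenius shift function
#'
#' Defines the horizontal (time) shift factor
#' \deqn{a_\theta(\theta) = \exp\left[\frac{E_a}{R}\left(\frac{1}{T_{ref}} -
#'   \frac{1}{\theta}\right)\right],}
#' with `a(t_ref) = 1` exactly and, for `ea > 0`, `a > 1` above the reference
#' temperature. Sign convention: `a_theta` multiplies time in the relaxation
#' modulus (equivalently divides the relaxation times), so relaxation
#' accelerates with temperature.
#'
#' @param ea Activation energy, J/mol, `>= 0`.
#' @param t_ref Reference temperature, K, `> 0`. Default 305.15 K (32 degrees
#'   Celsius, the reference used for master-curve assembly).
#' @return An object of class `arrhenius_shift` with fields `ea`, `t_ref`,
#'   `r_gas`.
#' @export
arrhenius_shift <- function(ea, t_ref = 305.15) {
  stopifnot_scalar(ea, "ea")
  stopifnot_scalar(t_ref, "t_ref")
  if (ea < 0) rheo_abort("activation energy must be >= 0", "rheo_domain_error")
  if (t_ref <= 0) {
    rheo_abort("reference temperature must be > 0 K", "rheo_domain_error")
  }
  structure(list(ea = as.numeric(ea), t_ref = as.numeric(t_ref),
                 r_gas = R_GAS),
            class = "arrhenius_shift")
}

#' Evaluate the Arrhenius shift factor
#'
#' @param shift An [arrhenius_shift()].
#' @param temperature Absolute temperature(s), K, `> 0`. Vectorized.
#' @return `a_theta(temperature)`, dimensionless, `> 0`.
#' @examples
#' sh <- arrhenius_shift(50000)
#' shift_factor(sh, 305.15)  # 1 at the reference temperature
#' @export
shift_factor <- function(shift, temperature) {
  stopifnot(inherits(shift, "arrhenius_shift"))
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    rheo_abort("temperature must be finite and > 0 K", "rheo_domain_error")
  }
  exp((shift$ea / shift$r_gas) * (1 / shift$t_ref - 1 / temperature))
}

#' @export
print.arrhenius_shift <- function(x, ...) {
  cat(sprintf(
    "Arrhenius shift: Ea = %.6g J/mol, T_ref = %.2f K (%.2f degC)\n",
    x$ea, x$t_ref, kelvin_to_celsius(x$t_ref)))
  invisible(x)
}
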