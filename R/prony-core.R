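# Closed-form time- and frequency-domain evaluation of the viscoelastic model.

#' Single Maxwell-element relaxation modulus
#'
#' The one-branch special case `G(t) = g0 * exp(-t / tau_theta)`, where `g0`
#' here multiplies the exponential (no additive equilibrium term). This is
#' kept as a distinct operation from [relaxation_modulus()], whose `g0` is an
#' additive equilibrium modulus; the two conventions coexist in the denture
#' adhesive modelling lineage and are not interchangeable.
#'
#' @param g0 Modulus at `t = 0`, Pa, `>= 0`.
#' @param tau_theta Relaxation time, s, `> 0`.
#' @param t Time(s), s, `>= 0`. Vectorized.
#' @return Modulus, Pa; non-increasing in `t`.
#' @export
maxwell_relaxation <- function(g0, tau_theta, t) {
  stopifnot_scalar(g0, "g0")
  stopifnot_scalar(tau_theta, "tau_theta")
  if (g0 < 0) rheo_abort("g0 must be >= 0", "rheo_domain_error")
  if (tau_theta <= 0) rheo_abort("tau_theta must be > 0", "rheo_domain_error")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    rheo_abort("t must be finite and >= 0", "rheo_domain_error")
  }
  g0 * exp(-t / tau_theta)
}

#' Prony-series relaxation modulus with temperature shift
#'
#' Evaluates
#' \deqn{G(t, \theta) = G_0 + \sum_i g_i
#'   \exp\left(-\frac{a_\theta(\theta)\, t}{\tau_i}\right).}
#'
#' @param prony A [prony_series()].
#' @param shift An [arrhenius_shift()].
#' @param t Time(s), s, `>= 0`. Vectorized.
#' @param temperature Absolute temperature, K. Defaults to the shift's
#'   reference temperature (where `a_theta = 1`).
#' @return Modulus, Pa; equals `g0 + sum(g)` at `t = 0` and tends to `g0` as
#'   `t` grows.
#' @export
relaxation_modulus <- function(prony, shift, t, temperature = shift$t_ref) {
  stopifnot(inherits(prony, "prony_series"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    rheo_abort("t must be finite and >= 0", "rheo_domain_error")
  }
  a <- shift_factor(shift, temperature)
  decay <- exp(outer(t, prony$tau, function(tt, tt_i) -a * tt / tt_i))
  drop(prony$g0 + decay %*% prony$g)
}

#' Storage modulus of the Prony series
#'
#' Frequency-domain interconversion of the generalized Maxwell model. With
#' effective relaxation times `tau_eff = tau / a_theta(theta)`,
#' \deqn{G'(\omega) = G_0 + \sum_i g_i
#'   \frac{(\omega\tau_i^{eff})^2}{1 + (\omega\tau_i^{eff})^2}.}
#' Non-decreasing in `omega`, with limits `g0` (static) and `g0 + sum(g)`
#' (glassy).
#'
#' @inheritParams relaxation_modulus
#' @param angular_frequency Angular frequency(ies) omega, rad/s, `>= 0`.
#' @return Storage modulus G', Pa.
#' @export
storage_modulus <- function(prony, shift, angular_frequency,
                            temperature = shift$t_ref) {
  stopifnot(inherits(prony, "prony_series"))
  check_omega(angular_frequency)
  a <- shift_factor(shift, temperature)
  wt <- outer(angular_frequency, prony$tau / a)
  drop(prony$g0 + (wt^2 / (1 + wt^2)) %*% prony$g)
}

#' Loss modulus of the Prony series
#'
#' \deqn{G''(\omega) = \sum_i g_i
#'   \frac{\omega\tau_i^{eff}}{1 + (\omega\tau_i^{eff})^2},}
#' with `tau_eff = tau / a_theta(theta)`. Each branch peaks at
#' `omega * tau_eff = 1` with value `g_i / 2`; the loss modulus vanishes in
#' both the static and glassy limits.
#'
#' @inheritParams storage_modulus
#' @return Loss modulus G'', Pa, `>= 0`.
#' @export
loss_modulus <- function(prony, shift, angular_frequency,
                         temperature = shift$t_ref) {
  stopifnot(inherits(prony, "prony_series"))
  check_omega(angular_frequency)
  a <- shift_factor(shift, temperature)
  wt <- outer(angular_frequency, prony$tau / a)
  drop((wt / (1 + wt^2)) %*% prony$g)
}

check_omega <- function(omega) {
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega < 0)) {
    rheo_abort("angular_frequency must be finite and >= 0",
               "rheo_domain_error")
  }
  invisible(omega)
}
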