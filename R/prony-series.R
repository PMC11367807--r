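# Discrete relaxation spectrum container (generalized Maxwell model).

#' Discrete Prony-series relaxation spectrum
#'
#' A generalized Maxwell model: an equilibrium spring `g0` in parallel with
#' `n` Maxwell branches, branch `i` having amplitude `g[i]` (Pa) and
#' relaxation time `tau[i]` (s). The relaxation modulus is
#' \deqn{G(t) = G_0 + \sum_{i=1}^n g_i \exp(-t/\tau_i).}
#' The instantaneous modulus is `g0 + sum(g)` and the equilibrium (fully
#' relaxed) modulus is `g0`.
#'
#' @param g0 Equilibrium modulus, Pa, `>= 0`.
#' @param g Numeric vector of branch amplitudes, Pa, all `>= 0`, length
#'   `n >= 1`.
#' @param tau Numeric vector of relaxation times, s, strictly positive and
#'   strictly increasing, same length as `g`.
#' @return An object of class `prony_series` with fields `g0`, `g`, `tau`,
#'   `n`.
#' @examples
#' ps <- prony_series(10, c(5, 3, 2), c(0.1, 1, 10))
#' instantaneous_modulus(ps)  # 20
#' @export
prony_series <- function(g0, g, tau) {
  stopifnot_scalar(g0, "g0")
  if (!is.numeric(g) || !is.numeric(tau) || length(g) == 0L ||
      length(g) != length(tau)) {
    rheo_abort("'g' and 'tau' must be numeric vectors of equal length >= 1",
               "rheo_domain_error")
  }
  if (any(!is.finite(g)) || any(!is.finite(tau))) {
    rheo_abort("Prony amplitudes and relaxation times must be finite",
               "rheo_domain_error")
  }
  if (g0 < 0 || any(g < 0)) {
    rheo_abort("moduli g0 and g_i must be non-negative", "rheo_domain_error")
  }
  if (any(tau <= 0)) {
    rheo_abort("relaxation times tau_i must be strictly positive",
               "rheo_domain_error")
  }
  if (length(tau) > 1L && any(diff(tau) <= 0)) {
    rheo_abort("relaxation times tau_i must be strictly increasing",
               "rheo_domain_error")
  }
  structure(
    list(g0 = as.numeric(g0), g = as.numeric(g), tau = as.numeric(tau),
         n = length(g)),
    class = "prony_series"
  )
}

#' @rdname prony_series
#' @param x A `prony_series`.
#' @export
instantaneous_modulus <- function(x) {
  stopifnot(inherits(x, "prony_series"))
  x$g0 + sum(x$g)
}

#' @export
print.prony_series <- function(x, ...) {
  cat(sprintf("Prony series: n = %d, G0 = %.6g Pa, G(0) = %.6g Pa\n",
              x$n, x$g0, instantaneous_modulus(x)))
  print(data.frame(i = seq_len(x$n), g_pa = x$g, tau_s = x$tau),
        row.names = FALSE)
  invisible(x)
}
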