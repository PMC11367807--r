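# Constrained fitting of the discrete relaxation spectrum to master-curve
# G'/G'' data: stage 1 non-negative linear least squares on a fixed
# log-spaced relaxation-time grid, optional stage 2 bounded nonlinear
# refinement of all parameters.

# design matrix of relative-weighted stacked G' and G'' residuals
prony_design <- function(omega, gp, gpp, tau) {
  wt <- outer(omega, tau)
  sto <- wt^2 / (1 + wt^2)
  los <- wt / (1 + wt^2)
  keep1 <- gp > 0
  keep2 <- gpp > 0
  parts <- list()
  if (any(keep1)) {
    parts$sto <- cbind(1, sto[keep1, , drop = FALSE]) / gp[keep1]
  }
  if (any(keep2)) {
    parts$los <- cbind(0, los[keep2, , drop = FALSE]) / gpp[keep2]
  }
  A <- do.call(rbind, unname(parts))
  list(A = A, b = rep(1, nrow(A)))
}

fit_rms <- function(prony, shift, omega, gp, gpp) {
  mp <- storage_modulus(prony, shift, omega)
  ml <- loss_modulus(prony, shift, omega)
  ok1 <- gp > 0 & mp > 0
  ok2 <- gpp > 0 & ml > 0
  r <- c(log10(mp[ok1] / gp[ok1]), log10(ml[ok2] / gpp[ok2]))
  sqrt(mean(r^2))
}

#' Fit a Prony series to a master curve
#'
#' Stage 1 places `n` relaxation times log-spaced across the reciprocal of
#' the reduced-frequency window, `[1/omega_max, 1/omega_min]`, and solves for
#' the equilibrium modulus `g0` and the branch amplitudes `g_i` by
#' non-negative least squares (Lawson-Hanson) on relatively weighted stacked
#' G' and G'' residuals. With `tau_policy = "refined"`, stage 2 then refines
#' `(g0, g_i, log tau_i)` by bounded Levenberg-Marquardt from the stage-1
#' start, each `tau_i` confined to one decade either side of its grid
#' position; refinements that cross or tie relaxation times are rejected.
#' The pipeline is deterministic: no random starts.
#'
#' @param master A `master_curve` from [build_master_curve()] (or any
#'   data.frame with columns `omega_reduced`, `g_prime_pa`,
#'   `g_double_prime_pa`), `>= 2n + 1` points spanning at least one decade.
#' @param n Number of Prony branches (default 3, the term count at which the
#'   adhesive's relaxation spectrum is adequately discretized).
#' @param tau_policy `"refined"` (default) or `"fixed"` (stage 1 only).
#' @param ridge Optional non-negative Tikhonov parameter added to the
#'   stage-1 normal system for ill-conditioned spectra; 0 (off) by default.
#' @return A `prony_fit`: list with `prony` (the fitted [prony_series()]),
#'   `residual_rms` (RMS log10 residual over the fitted points), `n_points`
#'   and `tau_policy`.
#' @export
fit_prony <- function(master, n = 3, tau_policy = c("refined", "fixed"),
                      ridge = 0) {
  tau_policy <- match.arg(tau_policy)
  df <- as.data.frame(master)
  need <- c("omega_reduced", "g_prime_pa", "g_double_prime_pa")
  if (!all(need %in% names(df))) {
    rheo_abort("master curve needs columns omega_reduced, g_prime_pa, g_double_prime_pa",
               "rheo_schema_error")
  }
  df <- df[order(df$omega_reduced), , drop = FALSE]
  m <- nrow(df)
  if (m < 2 * n + 1) {
    rheo_abort(sprintf("need at least %d points to fit n = %d branches",
                       2 * n + 1, n), "rheo_insufficient_data_error")
  }
  omega <- df$omega_reduced
  if (log10(max(omega) / min(omega)) < 1) {
    rheo_abort("master curve must span at least one frequency decade",
               "rheo_insufficient_data_error")
  }
  gp <- df$g_prime_pa
  gpp <- df$g_double_prime_pa
  if (all(gp <= 0) && all(gpp <= 0)) {
    rheo_abort("all moduli are zero; nothing to fit", "rheo_fit_error")
  }

  # midpoint-rule log spacing across [1/omega_max, 1/omega_min]: n cells,
  # one relaxation time at each cell centre (n = 1 is the window centre)
  lo <- log10(1 / max(omega))
  hi <- log10(1 / min(omega))
  tau <- 10^(lo + (hi - lo) * (seq_len(n) - 0.5) / n)

  des <- prony_design(omega, gp, gpp, tau)
  A <- des$A
  b <- des$b
  if (ridge > 0) {
    A <- rbind(A, sqrt(ridge) * diag(n + 1))
    b <- c(b, rep(0, n + 1))
  }
  sol <- pracma::lsqnonneg(A, b)$x
  g0 <- sol[1]
  g <- sol[-1]
  # NNLS can zero a branch; keep the series valid (g_i >= 0 is allowed)
  prony1 <- prony_series(g0, g, tau)
  unit <- arrhenius_shift(0)

  prony <- prony1
  if (tau_policy == "refined" && any(g > 0)) {
    # refine in log10 amplitude and log10 relaxation time: the mixed
    # Pa / decade scales of a raw parameterization stall the optimizer.
    # NNLS-silenced branches restart from a small amplitude floor.
    total <- g0 + sum(g)
    g_start <- pmax(g, 1e-8 * total)
    par0 <- c(g0, log10(g_start), log10(tau))
    lower <- c(0, log10(total) - 14 + numeric(n), log10(tau) - 1)
    upper <- c(Inf, log10(total) + 3 + numeric(n), log10(tau) + 1)
    resid_fn <- function(p) {
      ps <- list(g0 = p[1], g = 10^p[2:(n + 1)],
                 tau = 10^p[(n + 2):(2 * n + 1)], n = n)
      class(ps) <- "prony_series"
      mp <- storage_modulus(ps, unit, omega)
      ml <- loss_modulus(ps, unit, omega)
      c(((mp - gp) / pmax(gp, .Machine$double.eps))[gp > 0],
        ((ml - gpp) / pmax(gpp, .Machine$double.eps))[gpp > 0])
    }
    ref <- minpack.lm::nls.lm(par0, lower, upper, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, maxfev = 10000,
                                ftol = 1e-15, ptol = 1e-15))
    p <- ref$par
    tau_ref <- 10^p[(n + 2):(2 * n + 1)]
    if (n == 1 || all(diff(tau_ref) > 0)) {
      cand <- prony_series(p[1], 10^p[2:(n + 1)], tau_ref)
      # accept the refinement only if it does not worsen the fit
      if (fit_rms(cand, unit, omega, gp, gpp) <=
            fit_rms(prony1, unit, omega, gp, gpp)) {
        prony <- cand
      }
    }  # crossings/ties rejected: fall back to the stage-1 fit
  }

  structure(list(prony = prony,
                 residual_rms = fit_rms(prony, unit, omega, gp, gpp),
                 n_points = m, tau_policy = tau_policy),
            class = "prony_fit")
}

#' @export
print.prony_fit <- function(x, ...) {
  cat(sprintf("Prony fit (%s tau): %d points, RMS log10 residual %.3g\n",
              x$tau_policy, x$n_points, x$residual_rms))
  print(x$prony)
  invisible(x)
}
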