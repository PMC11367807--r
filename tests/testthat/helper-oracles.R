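# Independent oracles and fixture builders shared across the suite.

# Fourier-transform interconversion oracle, independent of the closed-form
# storage/loss implementation. For a decaying exponential branch the sine /
# cosine transforms are integrated numerically: the integrand is reduced to
# a single oscillation period (the trig factor is periodic, the exponential
# contributes an exact geometric tail sum); when the decay dies within one
# period the integral is truncated at 40 relaxation times instead.
osc_integral <- function(tau, omega, kind = c("sin", "cos")) {
  kind <- match.arg(kind)
  a <- 1 / tau
  if (omega == 0) return(if (kind == "sin") 0 else tau)
  f <- function(t) exp(-a * t) * (if (kind == "sin") sin(omega * t) else
    cos(omega * t))
  period <- 2 * pi / omega
  if (period >= 40 * tau) {
    stats::integrate(f, 0, 40 * tau, rel.tol = 1e-11,
                     subdivisions = 500L)$value
  } else {
    i0 <- stats::integrate(f, 0, period, rel.tol = 1e-11,
                           subdivisions = 500L)$value
    i0 / (1 - exp(-a * period))
  }
}

storage_oracle <- function(prony, omega) {
  prony$g0 + omega * sum(mapply(function(gi, ti)
    gi * osc_integral(ti, omega, "sin"), prony$g, prony$tau))
}

loss_oracle <- function(prony, omega) {
  omega * sum(mapply(function(gi, ti)
    gi * osc_integral(ti, omega, "cos"), prony$g, prony$tau))
}

# random valid Prony series over the decades probed by the standard sweep
random_prony <- function(n = sample(1:4, 1)) {
  prony_series(runif(1, 0, 500), runif(n, 10, 5000),
               sort(10^runif(n, -2, 2)))
}

# brute-force ordinary-least-squares oracle: explicit normal equations
ols_oracle <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  xtx <- t(Xi) %*% Xi
  beta <- solve(xtx, t(Xi) %*% y)
  res <- y - Xi %*% beta
  df <- nrow(Xi) - ncol(Xi)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(xtx)))
  tv <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tv,
       p = 2 * stats::pt(-abs(tv), df),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# the standard sweep frequency grid (0.01-10 Hz, 10 points/decade), Hz
sweep_freqs <- function() 10^(seq(-20L, 10L) / 10)

# the generator's covariate law, restated independently for truth checks
truth_params_for_test <- function(cfg, sr, ph) {
  list(g0 = cfg$truth_prony$g0,
       g = cfg$truth_prony$g * exp(cfg$beta_g * sr + cfg$gamma_g * (ph - 7)),
       tau = cfg$truth_prony$tau *
         exp(cfg$beta_tau * sr + cfg$gamma_tau * (ph - 7)))
}

expand_nodes <- function(srs, phs) {
  g <- expand.grid(sr = srs, ph = phs)
  lapply(seq_len(nrow(g)), function(i) c(g$sr[i], g$ph[i]))
}

# small deterministic sweep table fixture
toy_sweep <- function() {
  ps <- prony_series(400, c(3000, 1500, 800), c(0.05, 0.8, 12))
  sh <- arrhenius_shift(50000)
  f <- sweep_freqs()
  w <- hz_to_rad(f)
  sweep_table(data.frame(
    frequency_hz = f,
    g_prime_pa = storage_modulus(ps, sh, w),
    g_double_prime_pa = loss_modulus(ps, sh, w),
    temperature_c = 32, swelling_ratio = 0, ph = 7))
}
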