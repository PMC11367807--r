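# Synthetic frequency-sweep generator with known ground truth, emulating the
# oral-cavity rheometry design: 0.01-10 Hz at 10 points/decade, 17-52 degC in
# 5 degC steps, pH {2, 7, 10}, swelling in 20% steps to saturation.

#' Configuration of the synthetic rheometry generator
#'
#' Defines the ground-truth material and the experimental design the
#' generator emulates. Per-branch parameters vary log-linearly with the
#' covariates,
#' \deqn{\log g_i(SR, pH) = \log g_i^0 + \beta_{g,i}\,SR +
#'   \gamma_{g,i}\,(pH - 7),}
#' and analogously for the relaxation times, so positivity is automatic.
#' Measurement noise is multiplicative lognormal, parameterized
#' mean-unbiased, with coefficient of variation `noise_cv`, applied
#' independently to every G' and G'' cell.
#'
#' Defaults encode the study conditions: a 3-branch baseline spectrum with
#' paste-like kPa moduli and decade-separated relaxation times centred on
#' the 0.01-10 Hz window; activation energy 50 kJ/mol referenced to 32
#' degrees Celsius; temperature the dominant covariate, swelling moderate
#' and pH the weakest (|effect| ordering temperature > SR > pH); 2% relative
#' noise.
#'
#' @param truth_prony Baseline [prony_series()] at SR = 0, pH = 7.
#' @param truth_shift Ground-truth [arrhenius_shift()].
#' @param beta_g,beta_tau Per-branch log-linear slopes in SR (dimensionless
#'   per unit SR).
#' @param gamma_g,gamma_tau Per-branch log-linear slopes in (pH - 7) (per pH
#'   unit).
#' @param temperature_grid_c Test temperatures, degrees Celsius, strictly
#'   increasing.
#' @param frequency_grid_hz Sweep frequencies, Hz, strictly increasing.
#'   Default 0.01 to 10 Hz at 10 points/decade with both endpoints included
#'   (31 points).
#' @param ph_levels pH levels tested.
#' @param sr_levels Swelling-ratio levels tested (saturation mapped to 1).
#' @param noise_cv Relative measurement noise (coefficient of variation),
#'   `>= 0`.
#' @param seed Integer seed; mandatory, every run is deterministic given it.
#' @param design `"one_factor"`: one-factor-at-a-time series (temperature
#'   sweep at SR = 0, pH = 7; SR sweep and pH sweep at the reference
#'   temperature), or `"factorial"`: the full temperature x SR x pH cross.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    truth_prony = prony_series(400, c(3000, 1500, 800), c(0.05, 0.8, 12)),
    truth_shift = arrhenius_shift(50000, 305.15),
    beta_g = c(-0.35, -0.35, -0.35),
    beta_tau = c(-0.25, -0.25, -0.25),
    gamma_g = c(0.005, 0.005, 0.005),
    gamma_tau = c(0.002, 0.002, 0.002),
    temperature_grid_c = seq(17, 52, by = 5),
    frequency_grid_hz = 10^(seq(-20L, 10L) / 10),
    ph_levels = c(2, 7, 10),
    sr_levels = seq(0, 1, by = 0.2),
    noise_cv = 0.02,
    seed,
    design = c("one_factor", "factorial")) {
  design <- match.arg(design)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    rheo_abort("a scalar integer seed is mandatory", "rheo_config_error")
  }
  n <- truth_prony$n
  for (v in list(beta_g = beta_g, beta_tau = beta_tau, gamma_g = gamma_g,
                 gamma_tau = gamma_tau)) {
    if (length(v) != n || any(!is.finite(v))) {
      rheo_abort("covariate slopes must be finite, one per Prony branch",
                 "rheo_config_error")
    }
  }
  check_grid <- function(x, name) {
    if (length(x) == 0L || any(!is.finite(x)) ||
        (length(x) > 1L && any(diff(x) <= 0))) {
      rheo_abort(sprintf("'%s' must be non-empty and strictly increasing",
                         name), "rheo_config_error")
    }
  }
  check_grid(temperature_grid_c, "temperature_grid_c")
  check_grid(frequency_grid_hz, "frequency_grid_hz")
  check_grid(ph_levels, "ph_levels")
  check_grid(sr_levels, "sr_levels")
  if (noise_cv < 0) rheo_abort("noise_cv must be >= 0", "rheo_config_error")
  structure(list(
    truth_prony = truth_prony, truth_shift = truth_shift,
    beta_g = beta_g, beta_tau = beta_tau,
    gamma_g = gamma_g, gamma_tau = gamma_tau,
    temperature_grid_c = temperature_grid_c,
    frequency_grid_hz = frequency_grid_hz,
    ph_levels = ph_levels, sr_levels = sr_levels,
    noise_cv = noise_cv, seed = as.integer(seed), design = design),
    class = "generator_config")
}

# ground-truth branch parameters at a condition
truth_params <- function(config, sr, ph) {
  base <- config$truth_prony
  list(g0 = base$g0,
       g = base$g * exp(config$beta_g * sr + config$gamma_g * (ph - 7)),
       tau = base$tau * exp(config$beta_tau * sr +
                              config$gamma_tau * (ph - 7)))
}

#' Generate a synthetic sweep dataset with known ground truth
#'
#' Builds the condition grid of the configured design, evaluates the
#' noiseless storage/loss moduli from the ground-truth model, applies
#' mean-unbiased multiplicative lognormal noise, and returns both the sweep
#' table and the ground-truth [multiparam_model()] (its node table spans the
#' full SR x pH grid regardless of design). Deterministic given
#' `config$seed`; the caller's RNG state is restored on exit.
#'
#' @param config A [generator_config()].
#' @return A list with elements `table` (a [sweep_table()]) and `truth`
#'   (a [multiparam_model()]).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(config$seed)

  ref_c <- kelvin_to_celsius(config$truth_shift$t_ref)
  # snap the reference temperature onto the grid so the shared baseline
  # condition deduplicates exactly despite floating-point unit conversion
  near <- which.min(abs(config$temperature_grid_c - ref_c))
  if (abs(config$temperature_grid_c[near] - ref_c) < 1e-9) {
    ref_c <- config$temperature_grid_c[near]
  }
  conds <- switch(config$design,
    one_factor = unique(rbind(
      data.frame(temperature_c = config$temperature_grid_c,
                 swelling_ratio = min(config$sr_levels), ph = 7),
      data.frame(temperature_c = ref_c,
                 swelling_ratio = config$sr_levels, ph = 7),
      data.frame(temperature_c = ref_c,
                 swelling_ratio = min(config$sr_levels),
                 ph = config$ph_levels))),
    factorial = expand.grid(temperature_c = config$temperature_grid_c,
                            swelling_ratio = config$sr_levels,
                            ph = config$ph_levels)
  )

  omega <- hz_to_rad(config$frequency_grid_hz)
  sig <- sqrt(log(1 + config$noise_cv^2))
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    pp <- truth_params(config, conds$swelling_ratio[i], conds$ph[i])
    ps <- prony_series(pp$g0, pp$g, pp$tau)
    tk <- celsius_to_kelvin(conds$temperature_c[i])
    gp <- storage_modulus(ps, config$truth_shift, omega, tk)
    gpp <- loss_modulus(ps, config$truth_shift, omega, tk)
    if (sig > 0) {
      m <- length(omega)
      gp <- gp * exp(stats::rnorm(m, 0, sig) - sig^2 / 2)
      gpp <- gpp * exp(stats::rnorm(m, 0, sig) - sig^2 / 2)
    }
    rows[[i]] <- data.frame(
      frequency_hz = config$frequency_grid_hz,
      g_prime_pa = gp, g_double_prime_pa = gpp,
      temperature_c = conds$temperature_c[i],
      swelling_ratio = conds$swelling_ratio[i], ph = conds$ph[i])
  }
  tab <- sweep_table(do.call(rbind, rows),
                     provenance = sprintf("synthetic seed=%d design=%s",
                                          config$seed, config$design))

  grid <- expand.grid(sr = config$sr_levels, ph = config$ph_levels)
  nodes <- lapply(seq_len(nrow(grid)), function(i) {
    pp <- truth_params(config, grid$sr[i], grid$ph[i])
    list(sr = grid$sr[i], ph = grid$ph[i],
         prony = prony_series(pp$g0, pp$g, pp$tau))
  })
  truth <- multiparam_model(config$truth_shift, nodes,
                            retained_covariates = c("SR", "pH"))
  list(table = tab, truth = truth)
}
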