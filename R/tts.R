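# Time-temperature superposition: pairwise horizontal shift estimation,
# Arrhenius regression, master-curve assembly at the reference temperature.
#
# Convention (documented and tested): a_theta multiplies time in the
# relaxation modulus, so a sweep measured at theta equals the reference curve
# evaluated at omega / a_theta. Superposition therefore maps each record to
# the reduced frequency omega / a_theta(theta); curves measured above the
# reference temperature move toward lower reduced frequency. ShiftEstimate
# reports log10 a_theta(theta), which is positive above the reference
# temperature.

single_condition <- function(table, what) {
  df <- as.data.frame(table)
  if (nrow(unique(df[c("temperature_c", "swelling_ratio", "ph")])) != 1L) {
    rheo_abort(sprintf("%s must contain a single (temperature, SR, pH) condition",
                       what), "rheo_heterogeneous_condition_error")
  }
  df[order(df$frequency_hz), , drop = FALSE]
}

# summed squared log10-G' + log10-G'' residual of the target (frequencies
# multiplied by 10^m) against a log-log interpolant of the reference
shift_objective <- function(ref, tgt, m) {
  lf <- log10(tgt$frequency_hz) + m
  lref <- log10(ref$frequency_hz)
  ok <- lf >= min(lref) & lf <= max(lref)
  if (sum(ok) < 2L) return(list(value = Inf, n = sum(ok)))
  d1 <- stats::approx(lref, log10(ref$g_prime_pa), lf[ok])$y -
    log10(tgt$g_prime_pa[ok])
  d2 <- stats::approx(lref, log10(ref$g_double_prime_pa), lf[ok])$y -
    log10(tgt$g_double_prime_pa[ok])
  list(value = mean(c(d1^2, d2^2)), n = sum(ok))
}

#' Estimate the horizontal shift between two isothermal sweeps
#'
#' Finds the log10 frequency translation of the target sweep that minimizes
#' the summed squared log-G' plus log-G'' residual against a log-log
#' interpolant of the reference sweep over their overlap (coarse grid search
#' then local refinement; ties broken toward the smaller |shift|). The
#' returned `log10_shift` is `log10 a_theta` of the target temperature: the
#' negative of the frequency multiplier exponent, so it is positive for
#' temperatures above the reference.
#'
#' @param reference A single-condition [sweep_table()] (or subset) at the
#'   reference temperature, `>= 4` points.
#' @param target A single-condition sweep at the temperature whose shift is
#'   sought, `>= 4` points.
#' @param search_window Numeric length-2, the log10-shift search range.
#' @param grid_step Coarse search step in log10 units.
#' @return A `shift_estimate`: list with `temperature` (K), `log10_shift`,
#'   `overlap_rms` (RMS log10 residual over the overlap) and `n_overlap`.
#' @export
estimate_pairwise_shift <- function(reference, target,
                                    search_window = c(-6, 6),
                                    grid_step = 0.05) {
  ref <- single_condition(reference, "reference")
  tgt <- single_condition(target, "target")
  if (nrow(ref) < 4L || nrow(tgt) < 4L) {
    rheo_abort("both sweeps need at least 4 points",
               "rheo_insufficient_data_error")
  }
  grid <- seq(search_window[1], search_window[2], by = grid_step)
  grid <- grid[order(abs(grid))]  # ties resolve toward smaller |shift|
  vals <- vapply(grid, function(m) shift_objective(ref, tgt, -m)$value,
                 numeric(1))
  if (!any(is.finite(vals))) {
    rheo_abort("no overlap achievable within the search window",
               "rheo_no_overlap_error")
  }
  best <- grid[which.min(vals)]
  lo <- max(search_window[1], best - grid_step)
  hi <- min(search_window[2], best + grid_step)
  opt <- stats::optimize(function(m) shift_objective(ref, tgt, -m)$value,
                         c(lo, hi), tol = 1e-9)
  cand <- c(opt$minimum, best, if (0 >= lo && 0 <= hi) 0)
  cv <- vapply(cand, function(m) shift_objective(ref, tgt, -m)$value,
               numeric(1))
  keep <- which(cv <= min(cv) + 1e-15)
  s <- cand[keep][which.min(abs(cand[keep]))]
  res <- shift_objective(ref, tgt, -s)
  structure(list(temperature = celsius_to_kelvin(tgt$temperature_c[1]),
                 log10_shift = s,
                 overlap_rms = sqrt(res$value), n_overlap = res$n),
            class = "shift_estimate")
}

#' Estimate per-temperature shifts against a reference temperature
#'
#' Convenience wrapper: splits a multi-temperature single-(SR, pH) sweep
#' table by temperature and estimates every temperature's shift against the
#' reference sweep. The reference temperature's estimate is exactly zero.
#'
#' @param table A [sweep_table()] at a single (SR, pH).
#' @param reference_temperature_c Reference temperature, degrees Celsius;
#'   must be one of the measured temperatures.
#' @param ... Passed to [estimate_pairwise_shift()].
#' @return List of `shift_estimate` objects, one per temperature.
#' @export
estimate_shifts <- function(table, reference_temperature_c = 32, ...) {
  df <- as.data.frame(table)
  if (nrow(unique(df[c("swelling_ratio", "ph")])) != 1L) {
    rheo_abort("table must contain a single (SR, pH) condition",
               "rheo_heterogeneous_condition_error")
  }
  temps <- sort(unique(df$temperature_c))
  iref <- which(abs(temps - reference_temperature_c) < 1e-9)
  if (!length(iref)) {
    rheo_abort(sprintf("reference temperature %g degC not present in table",
                       reference_temperature_c),
               "rheo_missing_input_error")
  }
  ref <- df[df$temperature_c == temps[iref], , drop = FALSE]
  lapply(temps, function(tc) {
    if (tc == temps[iref]) {
      return(structure(list(temperature = celsius_to_kelvin(tc),
                            log10_shift = 0, overlap_rms = 0,
                            n_overlap = nrow(ref)),
                       class = "shift_estimate"))
    }
    estimate_pairwise_shift(ref, df[df$temperature_c == tc, , drop = FALSE],
                            ...)
  })
}

#' Fit the Arrhenius activation energy to estimated shifts
#'
#' Least-squares regression of `ln a_theta` on `(1/T_ref - 1/theta)` through
#' the origin; the slope is `Ea / R`.
#'
#' @param estimates List of `shift_estimate` objects at `>= 2` distinct
#'   temperatures.
#' @param t_ref Reference temperature, K.
#' @return An [arrhenius_shift()] with the fitted activation energy.
#' @export
fit_arrhenius <- function(estimates, t_ref = 305.15) {
  temps <- vapply(estimates, `[[`, numeric(1), "temperature")
  lsh <- vapply(estimates, `[[`, numeric(1), "log10_shift")
  if (length(unique(temps)) < 2L) {
    rheo_abort("need shift estimates at >= 2 distinct temperatures",
               "rheo_insufficient_data_error")
  }
  x <- 1 / t_ref - 1 / temps
  y <- lsh * log(10)
  nz <- abs(x) > 0
  if (!any(nz)) {
    rheo_abort("all estimates are at the reference temperature",
               "rheo_insufficient_data_error")
  }
  slope <- sum(x[nz] * y[nz]) / sum(x[nz]^2)
  arrhenius_shift(max(0, slope * R_GAS), t_ref)
}

#' Assemble a reference-temperature master curve
#'
#' Applies the horizontal shift only: each record's angular frequency is
#' divided by `a_theta(theta)` (the reduced frequency); moduli are left
#' unchanged, and reference-temperature records pass through unmodified.
#' Records from all temperatures are pooled and sorted by reduced frequency.
#'
#' @param table A multi-temperature [sweep_table()] at a single (SR, pH).
#' @param shift An [arrhenius_shift()] (typically from [fit_arrhenius()]).
#' @return A `master_curve`: data.frame with columns `omega_reduced` (rad/s),
#'   `g_prime_pa`, `g_double_prime_pa`, `temperature_c`, and attribute
#'   `reference_temperature` (K).
#' @export
build_master_curve <- function(table, shift) {
  df <- as.data.frame(table)
  if (nrow(df) == 0L) {
    rheo_abort("empty sweep table", "rheo_insufficient_data_error")
  }
  if (nrow(unique(df[c("swelling_ratio", "ph")])) != 1L) {
    rheo_abort("master curve input must share a single (SR, pH)",
               "rheo_heterogeneous_condition_error")
  }
  a <- shift_factor(shift, celsius_to_kelvin(df$temperature_c))
  out <- data.frame(omega_reduced = hz_to_rad(df$frequency_hz) / a,
                    g_prime_pa = df$g_prime_pa,
                    g_double_prime_pa = df$g_double_prime_pa,
                    temperature_c = df$temperature_c)
  out <- out[order(out$omega_reduced), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, reference_temperature = shift$t_ref,
            swelling_ratio = df$swelling_ratio[1], ph = df$ph[1],
            class = c("master_curve", "data.frame"))
}
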