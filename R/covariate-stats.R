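# Statistical screen: multiple linear regression of the moduli on
# temperature, swelling ratio and pH at 98% confidence, Pearson correlation
# matrix, and the covariate-retention decision that selects the pH-resolved
# or pH-free form of the material model.

screen_frame <- function(table, frequency = NULL, what = "table") {
  df <- as.data.frame(table)
  if (!is.null(frequency)) {
    hit <- abs(df$frequency_hz - frequency) <=
      1e-8 * max(frequency, .Machine$double.eps)
    if (!any(hit)) {
      rheo_abort(sprintf("frequency %g Hz not present in %s", frequency,
                         what), "rheo_missing_input_error")
    }
    df <- df[hit, , drop = FALSE]
  }
  df
}

#' Multiple linear regression of a modulus on the physiological covariates
#'
#' Ordinary least squares of the chosen response on temperature (degrees
#' Celsius), swelling ratio and pH, with intercept. Per-coefficient t
#' statistics and two-sided Student-t p-values are reported; a predictor is
#' flagged significant when `p < 1 - confidence` (0.02 at the default 98%
#' confidence level, i.e. the test of the null hypothesis that the predictor
#' does not influence the modulus). Adjusted R-squared is
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' By default all frequencies are pooled; `frequency` restricts the fit to a
#' single sweep frequency and `include_frequency` adds log10(frequency) as a
#' nuisance covariate, since pooled sweeps otherwise fold the whole
#' frequency dependence of the modulus into the residual. `log_response`
#' regresses log10 of the modulus (natural for multiplicative measurement
#' noise).
#'
#' @param table A [sweep_table()].
#' @param response `"g_prime"` or `"g_double_prime"`.
#' @param confidence Confidence level of the per-coefficient tests (default
#'   0.98).
#' @param log_response Regress log10(modulus) instead of the raw modulus.
#' @param frequency Optional single frequency (Hz) to restrict to.
#' @param include_frequency Add log10(frequency_hz) as a nuisance covariate.
#' @return An `mlr_result`: list with `coefficients` (data.frame: term,
#'   estimate, std_error, t_value, p_value, significant), `r_squared`,
#'   `adj_r_squared`, `confidence_level`, `n_obs`, `df_resid`, `response`,
#'   `degenerate` (TRUE when the residual variance is numerically zero, in
#'   which case p-values are NA).
#' @export
fit_mlr <- function(table, response = c("g_prime", "g_double_prime"),
                    confidence = 0.98, log_response = FALSE,
                    frequency = NULL, include_frequency = FALSE) {
  response <- match.arg(response)
  df <- screen_frame(table, frequency)
  y <- df[[paste0(response, "_pa")]]
  if (log_response) {
    if (any(y <= 0)) {
      rheo_abort("log_response requires strictly positive moduli",
                 "rheo_domain_error")
    }
    y <- log10(y)
  }
  X <- data.frame(temperature = df$temperature_c,
                  SR = df$swelling_ratio, pH = df$ph)
  if (include_frequency) X$log10_frequency <- log10(df$frequency_hz)
  p <- ncol(X)
  n <- nrow(X)
  if (n <= p + 1) {
    rheo_abort(sprintf("need more than %d observations for %d predictors",
                       p + 1, p), "rheo_insufficient_data_error")
  }
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  if (qr(M)$rank < ncol(M)) {
    rheo_abort("design matrix is singular (exactly collinear predictors)",
               "rheo_singular_design_error")
  }
  fit <- stats::lm(y ~ ., data = X)
  # summary() warns on numerically perfect fits; that case is detected and
  # reported through the degenerate flag instead
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  scale_y <- max(abs(y), .Machine$double.eps)
  degenerate <- sm$sigma < 1e-10 * scale_y
  alpha <- 1 - confidence
  coef_df <- data.frame(
    term = rownames(co),
    estimate = co[, 1],
    std_error = if (degenerate) NA_real_ else co[, 2],
    t_value = if (degenerate) NA_real_ else co[, 3],
    p_value = if (degenerate) NA_real_ else co[, 4],
    row.names = NULL)
  coef_df$significant <- !is.na(coef_df$p_value) & coef_df$p_value < alpha
  structure(list(coefficients = coef_df,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 confidence_level = confidence,
                 n_obs = n, df_resid = fit$df.residual,
                 response = response, log_response = log_response,
                 frequency = frequency, degenerate = degenerate),
            class = "mlr_result")
}

#' Pearson correlation matrix of covariates and moduli
#'
#' Sample Pearson r for every pair of {SR, temperature, pH, G', G''}:
#' symmetric, unit diagonal, entries in [-1, 1].
#'
#' @inheritParams fit_mlr
#' @param frequency Optional single frequency (Hz) to restrict to.
#' @return A `pearson_matrix`: the 5 x 5 correlation matrix with attribute
#'   `n_obs`.
#' @export
pearson_matrix <- function(table, frequency = NULL) {
  df <- screen_frame(table, frequency)
  vars <- data.frame(SR = df$swelling_ratio,
                     temperature = df$temperature_c,
                     pH = df$ph,
                     G_prime = df$g_prime_pa,
                     G_double_prime = df$g_double_prime_pa)
  if (nrow(vars) < 3L) {
    rheo_abort("need at least 3 observations for correlations",
               "rheo_insufficient_data_error")
  }
  sds <- vapply(vars, stats::sd, numeric(1))
  if (any(sds == 0)) {
    rheo_abort(sprintf("variable(s) with zero variance: %s",
                       paste(names(vars)[sds == 0], collapse = ", ")),
               "rheo_zero_variance_error")
  }
  r <- stats::cor(vars)
  structure(r, n_obs = nrow(vars), class = c("pearson_matrix", "matrix"))
}

#' Decide which covariates the material model retains
#'
#' A covariate is retained when it is significant (at the regressions'
#' confidence level) in at least one of the two modulus regressions AND its
#' strongest Pearson correlation with either modulus reaches `r_threshold`.
#' Temperature is always retained: it parameterizes the shift function, not
#' the node table. The result selects the pH-resolved form (`"sr_ph"`) when
#' pH survives, otherwise the simplified pH-free form (`"sr_only"`).
#'
#' @param reg_gprime,reg_gdoubleprime `mlr_result`s for G' and G'' computed
#'   on the same table.
#' @param pearson A [pearson_matrix()] computed on the same table.
#' @param r_threshold Minimum |r| against either modulus (default 0.3).
#' @return A `screen_result`: list with `retained` (character vector,
#'   always containing `"temperature"`), `model_form` (`"sr_ph"` or
#'   `"sr_only"`), and `evidence` (per-covariate significance and max |r|).
#' @export
screen_covariates <- function(reg_gprime, reg_gdoubleprime, pearson,
                              r_threshold = 0.3) {
  stopifnot(inherits(reg_gprime, "mlr_result"),
            inherits(reg_gdoubleprime, "mlr_result"),
            inherits(pearson, "pearson_matrix"))
  if (!identical(reg_gprime$response, "g_prime") ||
      !identical(reg_gdoubleprime$response, "g_double_prime")) {
    rheo_abort("regressions must be for g_prime and g_double_prime in that order",
               "rheo_consistency_error")
  }
  n <- c(reg_gprime$n_obs, reg_gdoubleprime$n_obs, attr(pearson, "n_obs"))
  if (length(unique(n)) != 1L) {
    rheo_abort("regressions and Pearson matrix were not computed on the same table",
               "rheo_consistency_error")
  }
  covs <- c("temperature", "SR", "pH")
  sig_in <- function(reg, term) {
    isTRUE(reg$coefficients$significant[reg$coefficients$term == term])
  }
  evidence <- data.frame(
    covariate = covs,
    significant = vapply(covs, function(cv)
      sig_in(reg_gprime, cv) || sig_in(reg_gdoubleprime, cv), logical(1)),
    max_abs_r = vapply(covs, function(cv)
      max(abs(pearson[cv, c("G_prime", "G_double_prime")])), numeric(1)),
    row.names = NULL)
  evidence$retained <- (evidence$significant &
                          evidence$max_abs_r >= r_threshold) |
    evidence$covariate == "temperature"
  retained <- evidence$covariate[evidence$retained]
  structure(list(retained = retained,
                 model_form = if ("pH" %in% retained) "sr_ph" else "sr_only",
                 r_threshold = r_threshold,
                 evidence = evidence),
            class = "screen_result")
}

#' @export
print.mlr_result <- function(x, ...) {
  cat(sprintf(
    "MLR of %s%s on temperature + SR + pH (n = %d, confidence %.0f%%)\n",
    if (x$log_response) "log10 " else "", x$response, x$n_obs,
    100 * x$confidence_level))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("R-squared %.4f, adjusted R-squared %.4f%s\n", x$r_squared,
              x$adj_r_squared,
              if (x$degenerate) " [degenerate: zero residual variance]" else ""))
  invisible(x)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Covariate screen (|r| threshold", x$r_threshold, ")\n")
  print(x$evidence, row.names = FALSE, digits = 3)
  cat("Retained:", paste(x$retained, collapse = ", "),
      "->", if (x$model_form == "sr_ph") "pH-resolved model"
      else "simplified pH-free model", "\n")
  invisible(x)
}
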