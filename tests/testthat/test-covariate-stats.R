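# Regression screen: OLS against the normal-equations oracle, Pearson
# matrix, covariate retention.

sweep_from_xy <- function(X, y1, y2 = y1) {
  sweep_table(data.frame(frequency_hz = seq_along(y1),
                         g_prime_pa = y1, g_double_prime_pa = y2,
                         temperature_c = X$temperature,
                         swelling_ratio = X$SR, ph = X$pH))
}

# sweep_table sorts records; recover the design in table order
design_of <- function(tab) {
  data.frame(temperature = tab$temperature_c, SR = tab$swelling_ratio,
             pH = tab$ph)
}

test_that("fit_mlr matches the brute-force normal-equations solve", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(10:40, 1)
    X <- data.frame(temperature = runif(n, 17, 52),
                    SR = runif(n), pH = runif(n, 2, 10))
    y <- 5 + 0.3 * X$temperature - 2 * X$SR + 0.1 * X$pH + rnorm(n)
    tab <- sweep_from_xy(X, abs(y) + 10)
    res <- fit_mlr(tab, "g_prime")
    orc <- ols_oracle(design_of(tab), tab$g_prime_pa)
    expect_equal(unname(res$coefficients$estimate), unname(orc$beta),
                 tolerance = 1e-9)
    expect_equal(res$coefficients$t_value, unname(orc$t), tolerance = 1e-9)
    expect_equal(res$coefficients$p_value, unname(orc$p), tolerance = 1e-9)
    expect_equal(res$r_squared, orc$r2, tolerance = 1e-9)
    expect_equal(res$adj_r_squared,
                 1 - (1 - orc$r2) * (n - 1) / (n - 3 - 1), tolerance = 1e-9)
  }
})

test_that("the 5-point hand-solved regression is reproduced", {
  # single informative predictor; slope/intercept solved by hand from the
  # normal equations: slope 19.9/10 = 1.99, intercept 5.02 - 1.99*2 = 1.04
  x <- c(0, 1, 2, 3, 4)
  y <- c(1.1, 2.9, 5.2, 6.8, 9.1)
  orc1 <- ols_oracle(data.frame(x = x), y)
  expect_equal(unname(orc1$beta), c(1.04, 1.99), tolerance = 1e-12)
  # and the package's design with the same response and varying nuisance
  set.seed(3)
  X <- data.frame(temperature = x, SR = runif(5), pH = runif(5, 2, 10))
  tab <- sweep_from_xy(X, y)
  res <- fit_mlr(tab, "g_prime")
  orc <- ols_oracle(design_of(tab), tab$g_prime_pa)
  expect_equal(unname(res$coefficients$estimate), unname(orc$beta),
               tolerance = 1e-9)
})

test_that("an exact linear law flags degenerate inference", {
  set.seed(22)
  X <- data.frame(temperature = runif(20, 17, 52), SR = runif(20),
                  pH = runif(20, 2, 10))
  y <- 1 + 2 * X$temperature
  res <- fit_mlr(sweep_from_xy(X, y), "g_prime")  # exact law survives sorting
  expect_true(res$degenerate)
  expect_equal(res$coefficients$estimate[
    res$coefficients$term == "temperature"], 2, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_true(all(is.na(res$coefficients$p_value)))
})

test_that("collinear designs and tiny samples are classed errors", {
  X <- data.frame(temperature = c(1, 2, 3, 4, 5, 6),
                  SR = c(1, 2, 3, 4, 5, 6) / 10, pH = 7)
  X$pH <- X$temperature * 2          # exact collinearity
  expect_error(fit_mlr(sweep_from_xy(X, rnorm(6) + 10), "g_prime"),
               class = "rheo_singular_design_error")
  X2 <- data.frame(temperature = 1:4, SR = c(0.1, 0.5, 0.2, 0.9),
                   pH = c(2, 7, 10, 5))
  expect_error(fit_mlr(sweep_from_xy(X2, rnorm(4) + 10), "g_prime"),
               class = "rheo_insufficient_data_error")
})

test_that("Pearson matrix reproduces hand cases and structure", {
  X <- data.frame(temperature = c(1, 2, 3), SR = c(0.2, 0.4, 0.6),
                  pH = c(6, 4, 2))
  tab <- sweep_from_xy(X, y1 = c(2, 4, 6), y2 = c(6, 4, 2))
  pm <- pearson_matrix(tab)
  expect_equal(unname(pm["SR", "G_prime"]), 1)
  expect_equal(unname(pm["pH", "G_prime"]), -1)
  expect_equal(unname(diag(pm)), rep(1, 5))
  expect_equal(unclass(pm), t(unclass(pm)), ignore_attr = TRUE)
  expect_true(all(abs(pm) <= 1 + 1e-12))
  # orthogonal-by-construction deviations
  x <- c(-1, 0, 1) + 5
  y <- c(1, -2, 1) + 5
  expect_equal(cor(x, y), 0)
})

test_that("Pearson matrix is invariant under affine rescaling", {
  set.seed(23)
  X <- data.frame(temperature = runif(20, 17, 52), SR = runif(20),
                  pH = runif(20, 2, 10))
  tab1 <- sweep_from_xy(X, runif(20, 100, 200), runif(20, 10, 50))
  # positive affine map of pH preserves the table's sort order, so rows
  # stay paired with the same modulus values
  X2 <- design_of(tab1)
  X2$pH <- 0.5 * X2$pH + 1
  tab2 <- sweep_from_xy(X2, tab1$g_prime_pa, tab1$g_double_prime_pa)
  expect_equal(unclass(pearson_matrix(tab1)), unclass(pearson_matrix(tab2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-variance variables are refused by name", {
  X <- data.frame(temperature = c(1, 2, 3, 4), SR = c(0.1, 0.3, 0.2, 0.4),
                  pH = 7)
  tab <- sweep_from_xy(X, c(10, 11, 12, 13))
  expect_error(pearson_matrix(tab), "pH",
               class = "rheo_zero_variance_error")
})

mock_mlr <- function(response, p_values) {
  structure(list(
    coefficients = data.frame(
      term = c("(Intercept)", "temperature", "SR", "pH"),
      estimate = 1, std_error = 1, t_value = 1,
      p_value = c(0.5, p_values),
      significant = c(0.5, p_values) < 0.02),
    r_squared = 0.8, adj_r_squared = 0.79, confidence_level = 0.98,
    n_obs = 144L, df_resid = 140L, response = response,
    log_response = FALSE, frequency = NULL, degenerate = FALSE),
    class = "mlr_result")
}

mock_pearson <- function(r_gp, r_gpp) {
  v <- c("SR", "temperature", "pH", "G_prime", "G_double_prime")
  r <- diag(5)
  dimnames(r) <- list(v, v)
  r[1:3, 4] <- r[4, 1:3] <- r_gp
  r[1:3, 5] <- r[5, 1:3] <- r_gpp
  structure(r, n_obs = 144L, class = c("pearson_matrix", "matrix"))
}

test_that("the weak-pH correlation pattern drops pH from the model", {
  # Pearson rows typical of this adhesive class: SR -0.269/0.361,
  # temperature -0.869/-0.65, pH -0.045/0.078; all predictors significant
  # in both regressions
  reg1 <- mock_mlr("g_prime", c(1e-4, 1e-4, 1e-4))
  reg2 <- mock_mlr("g_double_prime", c(1e-4, 1e-4, 1e-4))
  pm <- mock_pearson(c(-0.269, -0.869, -0.045), c(0.361, -0.65, 0.078))
  scr <- screen_covariates(reg1, reg2, pm)
  expect_setequal(scr$retained, c("temperature", "SR"))
  expect_identical(scr$model_form, "sr_only")
})

test_that("retention edge cases: everything kept, or temperature forced", {
  all_sig <- mock_mlr("g_prime", c(1e-4, 1e-4, 1e-4))
  all_sig2 <- mock_mlr("g_double_prime", c(1e-4, 1e-4, 1e-4))
  perfect <- mock_pearson(c(1, 1, 1), c(1, 1, 1))
  expect_setequal(screen_covariates(all_sig, all_sig2, perfect)$retained,
                  c("temperature", "SR", "pH"))
  none <- mock_mlr("g_prime", c(1, 1, 1))
  none2 <- mock_mlr("g_double_prime", c(1, 1, 1))
  scr <- screen_covariates(none, none2, perfect)
  expect_identical(scr$retained, "temperature")
  expect_identical(scr$model_form, "sr_only")
})

test_that("mismatched screen inputs are refused", {
  reg1 <- mock_mlr("g_prime", c(1e-4, 1e-4, 1e-4))
  reg2 <- mock_mlr("g_double_prime", c(1e-4, 1e-4, 1e-4))
  pm <- mock_pearson(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  attr(pm, "n_obs") <- 99L
  expect_error(screen_covariates(reg1, reg2, pm),
               class = "rheo_consistency_error")
  expect_error(screen_covariates(reg2, reg1, mock_pearson(
    c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))),
    class = "rheo_consistency_error")
})
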