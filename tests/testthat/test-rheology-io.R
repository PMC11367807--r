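# Readers/writers: sweep CSV round-trips, model JSON, FEM material card.

test_that("sweep CSV round-trips, including the empty table", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  empty <- sweep_table(data.frame(frequency_hz = numeric(0),
                                  g_prime_pa = numeric(0),
                                  g_double_prime_pa = numeric(0),
                                  temperature_c = numeric(0),
                                  swelling_ratio = numeric(0),
                                  ph = numeric(0)))
  write_sweep_table(empty, tmp)
  expect_identical(nrow(read_sweep_table(tmp)), 0L)

  one <- sweep_table(data.frame(frequency_hz = 0.01, g_prime_pa = 120,
                                g_double_prime_pa = 40, temperature_c = 32,
                                swelling_ratio = 0, ph = 7))
  write_sweep_table(one, tmp)
  back <- read_sweep_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(one), tolerance = 1e-9)
})

test_that("a generated temperature series round-trips with 248 records", {
  cfg <- generator_config(seed = 3, noise_cv = 0)
  tab <- generate_dataset(cfg)$table
  temp_series <- sweep_table(
    as.data.frame(tab)[tab$swelling_ratio == 0 & tab$ph == 7, ])
  expect_identical(nrow(temp_series), 8L * 31L)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_sweep_table(temp_series, tmp)
  back <- read_sweep_table(tmp)
  expect_identical(nrow(back), 248L)
  expect_equal(back$g_prime_pa, temp_series$g_prime_pa, tolerance = 1e-9)
})

test_that("schema, parse and integrity violations are classed errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frequency_hz,g_prime_pa", "1,2"), tmp)
  expect_error(read_sweep_table(tmp), "g_double_prime_pa",
               class = "rheo_schema_error")
  writeLines(c(paste("frequency_hz,g_prime_pa,g_double_prime_pa,",
                     "temperature_c,swelling_ratio,ph", sep = ""),
               "1,2,3,32,0,7", "2,oops,3,32,0,7"), tmp)
  expect_error(read_sweep_table(tmp), "row 2", class = "rheo_parse_error")
  df <- data.frame(frequency_hz = c(1, 1), g_prime_pa = 2,
                   g_double_prime_pa = 3, temperature_c = 32,
                   swelling_ratio = 0, ph = 7)
  expect_error(sweep_table(df), class = "rheo_integrity_error")
  df$frequency_hz <- c(1, NA)
  expect_error(sweep_table(df), class = "rheo_schema_error")
})

test_that("model JSON round-trips field-by-field", {
  sh <- arrhenius_shift(48237.123456789, 305.15)
  tmp <- withr::local_tempfile(fileext = ".json")

  minimal <- multiparam_model(sh, list(list(
    sr = 0, ph = NULL, prony = prony_series(1 / 3, 2 / 7, pi))),
    retained_covariates = "SR")
  write_model_json(minimal, tmp)
  back <- read_model_json(tmp)
  expect_equal(back$nodes[[1]]$prony$tau, pi, tolerance = 1e-13)
  expect_identical(back$retained_covariates, "SR")

  # pH-resolved flag and all 6 x 3 (g, tau) pairs preserved
  set.seed(5)
  nodes <- lapply(seq(0, 1, 0.2), function(s)
    list(sr = s, ph = NULL,
         prony = prony_series(runif(1), runif(3, 1, 10),
                              sort(10^runif(3, -1, 1)))))
  m6 <- multiparam_model(sh, nodes, retained_covariates = "SR")
  write_model_json(m6, tmp)
  b6 <- read_model_json(tmp)
  for (i in 1:6) {
    expect_equal(b6$nodes[[i]]$prony$g, m6$nodes[[i]]$prony$g,
                 tolerance = 1e-13)
    expect_equal(b6$nodes[[i]]$prony$tau, m6$nodes[[i]]$prony$tau,
                 tolerance = 1e-13)
  }

  grid <- expand.grid(sr = c(0, 1), ph = c(2, 7))
  ph_nodes <- lapply(1:4, function(i)
    list(sr = grid$sr[i], ph = grid$ph[i],
         prony = prony_series(1, 2, 3)))
  mph <- multiparam_model(sh, ph_nodes, retained_covariates = c("SR", "pH"))
  write_model_json(mph, tmp)
  expect_identical(sort(read_model_json(tmp)$retained_covariates),
                   c("SR", "pH"))
})

test_that("unsupported model versions are refused", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format_version": 99, "nodes": []}', tmp)
  expect_error(read_model_json(tmp), class = "rheo_version_error")
})

test_that("FEM card normalizes amplitudes and conserves total modulus", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  sh <- arrhenius_shift(50000)

  export_fem_card(prony_series(0, 100, 1), sh, tmp)
  expect_equal(read_fem_card(tmp)$alpha, 1)

  ps <- prony_series(10, c(5, 3, 2), c(0.1, 1, 10))
  export_fem_card(ps, sh, tmp)
  card <- read_fem_card(tmp)
  expect_equal(card$alpha, c(0.25, 0.15, 0.10), tolerance = 1e-14)
  expect_equal(sum(card$alpha) + card$prony$g0 / card$g_instantaneous, 1,
               tolerance = 1e-12)
  expect_equal(instantaneous_modulus(card$prony),
               instantaneous_modulus(ps), tolerance = 1e-9)
  expect_equal(card$shift$ea, sh$ea)

  expect_error(export_fem_card(prony_series(0, 0, 1), sh, tmp),
               class = "rheo_export_error")
})

test_that("round-trips hold under random models", {
  set.seed(9)
  tmp <- withr::local_tempfile(fileext = ".txt")
  sh <- arrhenius_shift(42000)
  for (rep in 1:10) {
    ps <- random_prony()
    export_fem_card(ps, sh, tmp)
    card <- read_fem_card(tmp)
    expect_equal(card$prony$g, ps$g, tolerance = 1e-9)
    expect_equal(card$prony$tau, ps$tau, tolerance = 1e-12)
    expect_true(all(card$alpha >= 0) && sum(card$alpha) <= 1 + 1e-12)
  }
})
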