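# Time-temperature superposition: pairwise shifts, Arrhenius regression,
# master-curve assembly.

noiseless_pair <- function(ea = 50000, theta_c = 42) {
  cfg <- generator_config(seed = 1, noise_cv = 0,
                          truth_shift = arrhenius_shift(ea))
  tab <- as.data.frame(generate_dataset(cfg)$table)
  base <- tab[tab$swelling_ratio == 0 & tab$ph == 7, ]
  list(ref = sweep_table(base[base$temperature_c == 32, ]),
       tgt = sweep_table(base[base$temperature_c == theta_c, ]),
       truth = cfg$truth_shift)
}

test_that("self-shift is exactly zero with zero residual", {
  p <- noiseless_pair()
  est <- estimate_pairwise_shift(p$ref, p$ref)
  expect_identical(est$log10_shift, 0)
  expect_identical(est$overlap_rms, 0)
})

test_that("a pure frequency translation is recovered with documented sign", {
  p <- noiseless_pair()
  shifted <- as.data.frame(p$ref)
  shifted$frequency_hz <- shifted$frequency_hz * 10
  est <- estimate_pairwise_shift(p$ref, sweep_table(shifted))
  # frequencies x10 superpose after division by 10, i.e. log10 a = +1
  expect_equal(est$log10_shift, 1, tolerance = 1e-6)
})

test_that("noiseless Arrhenius sweeps yield the closed-form shift", {
  p <- noiseless_pair(ea = 50000, theta_c = 42)
  est <- estimate_pairwise_shift(p$ref, p$tgt)
  expect_equal(est$log10_shift, log10(shift_factor(p$truth, 315.15)),
               tolerance = 1e-3)
})

test_that("estimated shifts are monotone in temperature (noiseless)", {
  cfg <- generator_config(seed = 1, noise_cv = 0)
  tab <- as.data.frame(generate_dataset(cfg)$table)
  base <- sweep_table(tab[tab$swelling_ratio == 0 & tab$ph == 7, ])
  ests <- estimate_shifts(base, 32)
  sh <- vapply(ests, `[[`, numeric(1), "log10_shift")
  expect_true(all(diff(sh) > 0))
})

test_that("Arrhenius regression recovers Ea from exact shifts", {
  truth <- arrhenius_shift(50000)
  temps <- celsius_to_kelvin(seq(17, 52, 5))
  ests <- lapply(temps, function(tk) list(
    temperature = tk, log10_shift = log10(shift_factor(truth, tk)),
    overlap_rms = 0))
  fit <- fit_arrhenius(ests, 305.15)
  expect_equal(fit$ea, 50000, tolerance = 1e-6)

  # all-zero shifts give Ea = 0
  zero <- lapply(temps, function(tk) list(temperature = tk,
                                          log10_shift = 0, overlap_rms = 0))
  expect_identical(fit_arrhenius(zero, 305.15)$ea, 0)

  # determined one-point solution
  one <- list(list(temperature = 315.15,
                   log10_shift = log10(shift_factor(truth, 315.15)),
                   overlap_rms = 0),
              list(temperature = 305.15, log10_shift = 0, overlap_rms = 0))
  expect_equal(fit_arrhenius(one, 305.15)$ea, 50000, tolerance = 1e-9)

  expect_error(fit_arrhenius(one[2], 305.15),
               class = "rheo_insufficient_data_error")
})

test_that("master curve is the horizontal reduction onto the truth curves", {
  cfg <- generator_config(seed = 1, noise_cv = 0)
  tab <- as.data.frame(generate_dataset(cfg)$table)
  base <- sweep_table(tab[tab$swelling_ratio == 0 & tab$ph == 7, ])
  mc <- build_master_curve(base, cfg$truth_shift)
  expect_identical(nrow(mc), nrow(base))          # point conservation
  expect_true(all(diff(mc$omega_reduced) >= 0))   # sorted
  # reference-temperature records pass through unmodified
  ref_rows <- mc[mc$temperature_c == 32, ]
  expect_equal(sort(ref_rows$omega_reduced),
               sort(hz_to_rad(base$frequency_hz[base$temperature_c == 32])),
               tolerance = 1e-14)
  # every reduced point lies on the reference-temperature model curve
  pred <- storage_modulus(cfg$truth_prony, cfg$truth_shift,
                          mc$omega_reduced)
  expect_equal(mc$g_prime_pa, pred, tolerance = 1e-9)
  predl <- loss_modulus(cfg$truth_prony, cfg$truth_shift, mc$omega_reduced)
  expect_equal(mc$g_double_prime_pa, predl, tolerance = 1e-9)
})

test_that("single-temperature input at the reference is returned unchanged", {
  p <- noiseless_pair()
  mc <- build_master_curve(p$ref, p$truth)
  expect_equal(mc$omega_reduced, hz_to_rad(p$ref$frequency_hz),
               tolerance = 1e-14)
  expect_equal(mc$g_prime_pa, p$ref$g_prime_pa)
})

test_that("mixed conditions and missing overlap are classed errors", {
  cfg <- generator_config(seed = 1, noise_cv = 0)
  tab <- as.data.frame(generate_dataset(cfg)$table)
  mixed <- sweep_table(tab[tab$temperature_c == 32 & tab$ph == 7, ])
  expect_error(build_master_curve(mixed, cfg$truth_shift),
               class = "rheo_heterogeneous_condition_error")
  p <- noiseless_pair()
  far <- as.data.frame(p$tgt)
  far$frequency_hz <- far$frequency_hz * 1e12
  expect_error(estimate_pairwise_shift(p$ref, sweep_table(far),
                                       search_window = c(-2, 2)),
               class = "rheo_no_overlap_error")
})
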