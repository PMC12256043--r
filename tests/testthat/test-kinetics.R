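test_that("standard-curve fit recovers exact calibration parameters", {
  conc <- 50 / 2^(0:12)
  sc <- fit_standard_curve(conc, 0.05 + 0.012 * conc)
  expect_s3_class(sc, "standard_curve")
  expect_equal(sc$slope, 0.012)
  expect_equal(sc$intercept, 0.05)
  expect_equal(sc$r_squared, 1)
  expect_error(fit_standard_curve(1:3, 1:2), "equal length")
  expect_error(fit_standard_curve(1:2, 1:2), "at least 3")
  expect_error(fit_standard_curve(c(2, 2, 2), c(1, 1, 1)), "degenerate")
})

test_that("absorbance_to_rate inverts the generator's forward model", {
  sc <- fit_standard_curve(c(1, 2, 4, 8), 0.05 + 0.012 * c(1, 2, 4, 8))
  v <- 0.05 # uM/s
  A <- 0.05 + 0.012 * (2 * v * 1800)
  expect_equal(absorbance_to_rate(A, 0, sc, incubation_s = 1800), v)
  # pi_per_turnover = 1 doubles the apparent rate
  expect_equal(absorbance_to_rate(A, 0, sc, 1800, pi_per_turnover = 1), 2 * v)
  # background shifts subtract linearly
  expect_equal(absorbance_to_rate(A + 0.1, 0.1, sc, 1800), v)
  # negative net absorbance floors at 0 with a warning
  expect_warning(r0 <- absorbance_to_rate(0.01, 0.2, sc, 1800), "floored")
  expect_equal(r0, 0)
  expect_error(absorbance_to_rate(A, 0, sc, incubation_s = 0), "incubation_s")
})

test_that("Michaelis-Menten fit recovers noiseless parameters exactly", {
  d <- mm_rates(km = 7.809, vmax = 0.2038)
  fit <- fit_michaelis_menten(d)
  expect_s3_class(fit, "mm_fit")
  expect_true(fit$converged)
  expect_equal(fit$km_uM, 7.809, tolerance = 1e-8)
  expect_equal(fit$vmax_uM_per_s, 0.2038, tolerance = 1e-8)
  expect_equal(round_half_up(fit$kcat_per_s, 4), 0.0204)
})

test_that("fit is equivariant under rate and substrate rescaling", {
  d <- mm_rates(km = 12.5, vmax = 0.08)
  base <- fit_michaelis_menten(d)
  # scale rates by c -> Vmax scales by c, Km unchanged
  d2 <- d
  d2$rate_uM_per_s <- 5 * d2$rate_uM_per_s
  f2 <- fit_michaelis_menten(d2)
  expect_equal(f2$vmax_uM_per_s, 5 * base$vmax_uM_per_s, tolerance = 1e-7)
  expect_equal(f2$km_uM, base$km_uM, tolerance = 1e-7)
  # scale substrate by c -> Km scales by c (need matching generative rates)
  d3 <- mm_rates(km = 3 * 12.5, vmax = 0.08,
                 S = 3 * default_substrate_series())
  f3 <- fit_michaelis_menten(d3)
  expect_equal(f3$km_uM, 3 * base$km_uM, tolerance = 1e-6)
})

test_that("optimiser agrees with an independent grid-search oracle", {
  sim <- gen_kinetics_plate(km_uM = 7.809, vmax_uM_per_s = 0.2038,
                            noise_cv = 0.05, seed = 17)
  rates <- suppressWarnings(process_kinetics_plate(sim$plate))$rates
  fit <- fit_michaelis_menten(rates)
  oracle <- mm_grid_oracle(rates$substrate_uM, rates$rate_uM_per_s,
                           km_range = c(0.5, 80), vmax_range = c(0.02, 2))
  # optimiser must be at least as good as the best grid point, and the grid
  # optimum must sit within one grid step of the optimiser's answer
  S <- rates$substrate_uM
  v <- rates$rate_uM_per_s
  sse_fit <- sum((v - fit$vmax_uM_per_s * S / (fit$km_uM + S))^2)
  expect_lte(sse_fit, oracle$sse + 1e-12)
  expect_lt(abs(log(oracle$km / fit$km_uM)), log(oracle$km_step) * 1.5)
  expect_lt(abs(log(oracle$vmax / fit$vmax_uM_per_s)),
            log(oracle$vmax_step) * 1.5)
})

test_that("fit_michaelis_menten validates inputs", {
  d <- mm_rates(5, 0.1)
  expect_error(fit_michaelis_menten(d[, 1, drop = FALSE]), "columns")
  expect_error(fit_michaelis_menten(d[1:4, ]), "5 distinct")
  bad <- d; bad$substrate_uM[1] <- -1
  expect_error(fit_michaelis_menten(bad), "positive")
  zero <- d; zero$rate_uM_per_s <- 0
  expect_error(fit_michaelis_menten(zero), "zero")
})

test_that("compute_kcat applies E0 division and half-away-from-zero rounding", {
  expect_equal(compute_kcat(0.2038), 0.0204)
  expect_equal(compute_kcat(0.1895), 0.019) # 0.01895 rounds up, not to even
  expect_equal(compute_kcat(0.2038, enzyme_conc = 0.2038), 1)
  expect_equal(compute_kcat(0.2038, digits = NULL), 0.02038)
  expect_error(compute_kcat(0.1, enzyme_conc = 0), "enzyme_conc")
})

test_that("plate processing recovers generative rates without noise", {
  sim <- gen_kinetics_plate(km_uM = 7.809, vmax_uM_per_s = 0.2038,
                            noise_cv = 0, replicates = 3)
  out <- process_kinetics_plate(sim$plate)
  expect_equal(out$standard_curve$slope, 0.012, tolerance = 1e-12)
  expected <- mm_rates(7.809, 0.2038)
  got <- dplyr::arrange(out$rates, dplyr::desc(substrate_uM))
  expect_equal(got$rate_uM_per_s, expected$rate_uM_per_s, tolerance = 1e-10)
  # background wells are absorbed: adding a constant to every well cancels
  shifted <- sim$plate
  shifted$absorbance <- shifted$absorbance + 0.07
  out2 <- process_kinetics_plate(shifted)
  expect_equal(out2$rates$rate_uM_per_s, out$rates$rate_uM_per_s,
               tolerance = 1e-10)
  expect_error(process_kinetics_plate(sim$plate[sim$plate$role == "sample", ]),
               "standard")
})

test_that("Km is recovered within a few percent at 5% multiplicative noise", {
  kms <- vapply(1:50, function(i) {
    sim <- gen_kinetics_plate(km_uM = 7.809, vmax_uM_per_s = 0.2038,
                              noise_cv = 0.05, seed = 100 + i)
    rates <- suppressWarnings(process_kinetics_plate(sim$plate))$rates
    fit_michaelis_menten(rates)$km_uM
  }, numeric(1))
  expect_lt(abs(median(kms) - 7.809) / 7.809, 0.05)
})

test_that("summarize_panel collates fits and reports kcat extremes", {
  fits <- list(
    fit_michaelis_menten(dplyr::mutate(mm_rates(7.809, 0.2038),
                                       enzyme_id = "e1", substrate = "GPP")),
    fit_michaelis_menten(dplyr::mutate(mm_rates(11.67, 0.124),
                                       enzyme_id = "e2", substrate = "FPP"))
  )
  panel <- summarize_panel(fits)
  expect_equal(nrow(panel$table), 2)
  expect_equal(panel$n_converged, 2L)
  expect_equal(panel$kcat_min, 0.0124)
  expect_equal(panel$kcat_max, 0.0204)
  expect_equal(panel$table$enzyme_id, c("e1", "e2"))
  expect_error(summarize_panel(list()), "at least one")
})

test_that("units audit: kcat is dimensionally Vmax over enzyme concentration", {
  # express the same system in nM: Vmax 203.8 nM/s, E0 10000 nM -> same kcat
  expect_equal(compute_kcat(0.2038, 10), compute_kcat(203.8, 10000))
  # rate conversion carries 1/s through: doubling incubation halves the rate
  sc <- fit_standard_curve(c(1, 2, 4), 0.012 * c(1, 2, 4))
  A <- 0.012 * 2 * 0.05 * 1800
  expect_equal(absorbance_to_rate(A, 0, sc, 3600),
               absorbance_to_rate(A, 0, sc, 1800) / 2)
})
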