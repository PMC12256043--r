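test_that("both Tm methods recover generative midpoints on noiseless curves", {
  for (tm in c(45.5, 65, 83.18)) {
    sim <- gen_melt_curve(tm_C = tm, noise_sd = 0)
    boltz <- estimate_tm(sim$curve, method = "boltzmann")
    expect_true(boltz$transition_detected)
    expect_equal(boltz$tm_C, tm, tolerance = 1e-4)
    deriv <- estimate_tm(sim$curve, method = "derivative")
    expect_true(deriv$transition_detected)
    # the derivative method is grid-limited to +/- 1 degC
    expect_lt(abs(deriv$tm_C - tm), 1 + 1e-8)
  }
})

test_that("derivative method hits a symmetric sigmoid midpoint exactly", {
  # with slope_post = 0 the model is a pure sigmoid + linear baseline; for an
  # on-grid midpoint the smoothed derivative peaks exactly there
  sim <- gen_melt_curve(tm_C = 60, slope_post = 0, slope_pre = 0, noise_sd = 0)
  res <- estimate_tm(sim$curve, method = "derivative")
  expect_identical(res$tm_C, 60)
})

test_that("Boltzmann Tm is robust to noise (<= 0.3 degC in >= 95% of curves)", {
  errs <- vapply(1:100, function(i) {
    sim <- gen_melt_curve(tm_C = 70.37, noise_sd = 20, seed = i)
    res <- estimate_tm(sim$curve)
    if (!res$transition_detected) return(NA_real_)
    abs(res$tm_C - 70.37)
  }, numeric(1))
  expect_true(all(!is.na(errs)))
  expect_gte(mean(errs <= 0.3), 0.95)
})

test_that("Tm estimates are invariant to affine fluorescence rescaling", {
  sim <- gen_melt_curve(tm_C = 72.4, noise_sd = 8, seed = 3)
  base <- estimate_tm(sim$curve)
  scaled <- sim$curve
  scaled$fluorescence <- 3.7 * scaled$fluorescence + 250
  res <- estimate_tm(scaled)
  expect_equal(res$tm_C, base$tm_C, tolerance = 1e-6)
})

test_that("flat and edge-transition curves are reported as transition-absent", {
  flat <- gen_melt_curve(tm_C = 70, amplitude = 0, no_transition = TRUE)
  for (m in c("boltzmann", "derivative")) {
    res <- estimate_tm(flat$curve, method = m)
    expect_false(res$transition_detected)
    expect_true(is.na(res$tm_C))
  }
  # noisy flat curve: amplitude must clear 3x RMSE
  noisy_flat <- gen_melt_curve(tm_C = 70, amplitude = 0, no_transition = TRUE,
                               noise_sd = 40, seed = 7)
  expect_false(estimate_tm(noisy_flat$curve)$transition_detected)
  # transition at the very edge of the range
  edge <- gen_melt_curve(tm_C = 94, noise_sd = 0)
  expect_false(estimate_tm(edge$curve)$transition_detected)
})

test_that("estimate_tm validates input shape", {
  sim <- gen_melt_curve(tm_C = 70)
  expect_error(estimate_tm(sim$curve[c("temperature_C", "fluorescence")]),
               "columns")
  short <- sim$curve[1:5, ]
  expect_error(estimate_tm(short), "at least 10")
  shuffled <- sim$curve[c(2, 1, 3:76), ]
  expect_error(estimate_tm(shuffled), "increasing")
})

test_that("compute_delta_tm is antisymmetric and NA-propagating", {
  a <- c(83.18, 70, NA, 76.46)
  b <- c(76.46, 76.46, 70, NA)
  expect_equal(compute_delta_tm(a, b), -compute_delta_tm(b, a))
  expect_equal(compute_delta_tm(83.18, 76.46), 6.72)
  expect_true(all(is.na(compute_delta_tm(a, b)[3:4])))
  expect_equal(compute_delta_tm(a, a), c(0, 0, NA, 0))
})

test_that("delta_tm_table applies the strict > 4 degC stabilisation rule", {
  tm <- tibble::tibble(
    condition_id = c("water_control", "c1", "c2", "c3", "c4"),
    protein_id = "p1",
    tm_C = c(76.46, 83.18, 80.46, 80.47, NA),
    method = "boltzmann", amplitude_AU = 1000, fit_rmse = 0.1,
    transition_detected = !is.na(c(76.46, 83.18, 80.46, 80.47, NA))
  )
  tab <- delta_tm_table(tm)
  expect_equal(nrow(tab), 4) # reference excluded
  expect_equal(tab$delta_tm_C[tab$condition_id == "c1"], 6.72)
  # exactly +4.00 is NOT stabilising; +4.01 is
  expect_false(tab$stabilising[tab$condition_id == "c2"])
  expect_true(tab$stabilising[tab$condition_id == "c3"])
  expect_true(tab$no_transition[tab$condition_id == "c4"])
  expect_false(tab$stabilising[tab$condition_id == "c4"])
  expect_error(delta_tm_table(tm, reference_id = "nope"), "nope")
})

test_that("rank_buffers takes per-condition medians with NA exclusion counts", {
  entries <- tibble::tibble(
    condition_id = rep(c("c1", "c2", "c3"), each = 3),
    protein_id = rep(c("p1", "p2", "p3"), 3),
    delta_tm_C = c(5, 6, 7,      # c1: median 6
                   1, NA, 9,     # c2: median 5 over 2 proteins, 1 excluded
                   NA, NA, NA)   # c3: no usable shift
  )
  rk <- rank_buffers(entries)
  expect_equal(rk$condition_id, c("c1", "c2", "c3"))
  expect_equal(rk$median_delta_tm_C, c(6, 5, NA))
  expect_equal(rk$n_no_transition, c(0L, 1L, 3L))
  expect_equal(rk$stabilising, c(TRUE, TRUE, FALSE))
  # ties break deterministically on condition id
  tie <- tibble::tibble(condition_id = c("b", "a"), protein_id = "p1",
                        delta_tm_C = c(2, 2))
  expect_equal(rank_buffers(tie)$condition_id, c("a", "b"))
  expect_error(rank_buffers(entries[0, ]), "non-empty")
})

test_that("best_condition_per_protein picks the top shift, flags 'none'", {
  entries <- tibble::tibble(
    condition_id = rep(c("c1", "c2"), 2),
    protein_id = rep(c("p1", "p2"), each = 2),
    tm_C = c(80, 84, NA, NA),
    delta_tm_C = c(3.5, 7.5, NA, NA)
  )
  best <- best_condition_per_protein(entries)
  expect_equal(best$best_condition[best$protein_id == "p1"], "c2")
  expect_equal(best$delta_tm_C[best$protein_id == "p1"], 7.5)
  expect_equal(best$best_condition[best$protein_id == "p2"], "none")
  expect_true(is.na(best$tm_C[best$protein_id == "p2"]))
})

test_that("the default buffer screen is the 8 x (1 + 3 x 3) = 80 design", {
  scr <- make_buffer_screen()
  expect_equal(nrow(scr), 80)
  expect_equal(anyDuplicated(scr$condition_id), 0L)
  expect_equal(nrow(default_screen_buffers()), 8)
  expect_equal(sum(is.na(scr$salt)), 8)              # one no-salt per buffer
  expect_equal(sort(unique(scr$salt_mM)), c(0, 50, 100, 200))
  expect_true(all(scr$buffer_mM == 200))
  counts <- table(scr$salt, useNA = "ifany")
  expect_true(all(counts[c("NaCl", "KCl", "MgCl2")] == 24))
  # cardinality identity under different inputs
  scr2 <- make_buffer_screen(buffers = tibble::tibble(buffer = "Tris", pH = 8),
                             salts = c("NaCl", "KCl"), salt_mM = c(100, 200))
  expect_equal(nrow(scr2), 1 * (1 + 2 * 2))
  expect_error(make_buffer_screen(buffers = default_screen_buffers()[0, ]),
               "non-empty")
  dup <- default_screen_buffers()[c(1, 1), ]
  expect_error(make_buffer_screen(buffers = dup), "Duplicate")
})

test_that("end-to-end screen analysis recovers the simulated ranking", {
  shifts <- setNames(c(6.72, 2.0, -1.5, 5.1), c("c1", "c2", "c3", "c4"))
  sim <- gen_buffer_screen_dataset(shifts, ref_tm_C = 76.46, noise_sd = 10,
                                   seed = 42)
  tab <- delta_tm_table(estimate_tm(sim$curves))
  rk <- rank_buffers(tab)
  expect_equal(rk$condition_id[1], "c1")
  expect_equal(rk$condition_id[rk$stabilising], c("c1", "c4"))
  best <- best_condition_per_protein(tab)
  expect_equal(best$best_condition, "c1")
  expect_equal(best$delta_tm_C, 6.72, tolerance = 0.3)
})
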