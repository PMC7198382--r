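test_that("uptake generator encodes the stated compartment split", {
  tc <- gen_uptake_timecourse(rng_seed = 1, noise_cv = 0)
  truth <- attr(tc, "truth")
  at2 <- truth[truth$time_h == 2, ]
  total2 <- at2$membrane_Bq + at2$cytoplasm_Bq + at2$nucleus_Bq
  expect_equal(total2, 57e-3, tolerance = 1e-9)          # 57 mBq/cell at 2 h
  expect_equal(at2$cytoplasm_Bq / total2, 0.13)          # 13% cytoplasm
  expect_lt(at2$nucleus_Bq / total2, 0.001)              # < 0.1% nucleus
  # receptor-negative scenario sits in the nonspecific band
  lo <- gen_uptake_timecourse(rng_seed = 1, total_mBq_per_cell_2h = 7.5,
                              noise_cv = 0)
  t2 <- attr(lo, "truth")[attr(lo, "truth")$time_h == 2, ]
  expect_lt(t2$membrane_Bq + t2$cytoplasm_Bq + t2$nucleus_Bq, 9e-3)
  expect_gt(t2$membrane_Bq + t2$cytoplasm_Bq + t2$nucleus_Bq, 6e-3)
  expect_error(gen_uptake_timecourse(cytoplasm_frac = 0.9,
                                     nucleus_frac = 0.2), "sum")
  # configured fractions propagate exactly
  cfg <- gen_uptake_timecourse(rng_seed = 2, cytoplasm_frac = 0.1,
                               nucleus_frac = 0, noise_cv = 0)
  tr <- attr(cfg, "truth")
  expect_equal(tr$cytoplasm_Bq,
               0.1 * (tr$membrane_Bq + tr$cytoplasm_Bq + tr$nucleus_Bq))
  expect_equal(tr$nucleus_Bq, rep(0, nrow(tr)))
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_uptake_timecourse(rng_seed = 7),
                   gen_uptake_timecourse(rng_seed = 7))
  expect_identical(gen_survival_data(rng_seed = 7),
                   gen_survival_data(rng_seed = 7))
  expect_identical(gen_tac_cohort(rng_seed = 7, n_animals = 3),
                   gen_tac_cohort(rng_seed = 7, n_animals = 3))
  expect_identical(gen_phantom_series(rng_seed = 7),
                   gen_phantom_series(rng_seed = 7))
  expect_identical(gen_tumor_maps(rng_seed = 7),
                   gen_tumor_maps(rng_seed = 7))
  s1 <- gen_micrographs(rng_seed = 7, n_nuclei = 4, nuclei_per_image = 4)
  s2 <- gen_micrographs(rng_seed = 7, n_nuclei = 4, nuclei_per_image = 4)
  expect_identical(s1$micrographs[[1]]$foci, s2$micrographs[[1]]$foci)
  expect_identical(s1$truth, s2$truth)
})

test_that("survival generator respects degenerate and recoverable truths", {
  flat <- gen_survival_data(rng_seed = 3, alpha = 0, beta = 0,
                            cells_plated = 5000)
  sf <- surviving_fraction(flat)
  expect_true(all(abs(sf$sf - 1) < 4 * sf$se + 0.02))
  expect_error(gen_survival_data(alpha = -0.1), ">= 0")

  ds <- gen_survival_data(rng_seed = 11, alpha = 0.3, beta = 0.03,
                          cells_plated = 4000, replicates = 4)
  fit <- fit_lq(surviving_fraction(ds))
  expect_equal(fit$alpha, 0.3, tolerance = 0.2)
  expect_equal(fit$beta, 0.03, tolerance = 0.4)
  expect_equal(fit$d90_Gy, attr(ds, "truth")$d90_Gy, tolerance = 0.05)
})

test_that("micrograph generator hits its configured count distribution", {
  sim <- gen_micrographs(rng_seed = 20, n_nuclei = 500, foci_mean = 67,
                         foci_sd = 18, nucleus_radius_px = 30)
  expect_equal(mean(sim$truth$true_count), 67, tolerance = 0.05)
  expect_equal(sd(sim$truth$true_count), 18, tolerance = 0.2)
  # zero-mean scenario: no foci anywhere
  blank <- gen_micrographs(rng_seed = 21, n_nuclei = 5, foci_mean = 0,
                           foci_sd = 0, nuclei_per_image = 5)
  expect_true(all(blank$truth$true_count == 0))
  expect_null(blank$positions)
})

test_that("TAC cohort matches its configured kinetics", {
  # noiseless single curve is exactly exponential
  one <- gen_tac_cohort(rng_seed = 5, n_animals = 1, t_bio_cv = 0,
                        noise_cv = 0)[[1]]
  fit <- fit_monoexp(one, lu177)
  expect_equal(fit$t_eff_h, 46.3, tolerance = 0.002)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # %ID normalisation: the mean curve passes 36 %ID/mL at 24 h
  a24 <- one$activity[one$times_h == 24]
  expect_equal(a24 / 20 * 100 / 0.177, 36, tolerance = 1e-6)
  # per-animal biological half-lives spread as configured
  coh <- gen_tac_cohort(rng_seed = 6, n_animals = 200, t_bio_cv = 0.25,
                        noise_cv = 0)
  tb <- attr(coh, "truth")$t_bios_h
  expect_equal(mean(tb), 65.2, tolerance = 0.05)
  expect_equal(sd(tb) / mean(tb), 0.25, tolerance = 0.2)
})

test_that("phantom generator spans the ladder and zero tubes stay zero", {
  ph <- gen_phantom_series(rng_seed = 4, poisson = FALSE)
  expect_equal(ph$A_In_MBq[1] > 0 && ph$A_Lu_MBq[1] == 0, TRUE)
  n <- nrow(ph)
  expect_true(ph$A_In_MBq[n] == 0 && ph$A_Lu_MBq[n] > 0)
  # pure-In tube: Lu-window counts are crosstalk only; a zero-activity
  # isotope contributes nothing
  expect_equal(ph$counts_In_window[n],
               round(attr(ph, "truth")$M_true[1, 2] * ph$A_Lu_MBq[n]))
})

test_that("tumor map generator exposes its ground-truth link", {
  pair <- gen_tumor_maps(rng_seed = 9, breakpoint = Inf, noise_sd = 0)
  # identity-slope link with no noise: scatter sits on the line
  m <- pair$mask
  expect_equal(pair$map_b[m], pmin(pair$map_a[m], Inf), tolerance = 1e-12)
  truth <- attr(gen_tumor_maps(rng_seed = 10), "truth")
  expect_equal(truth$breakpoint, 20)
})
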