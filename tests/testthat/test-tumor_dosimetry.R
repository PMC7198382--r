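test_that("mono-exponential fit recovers the effective half-life", {
  # T_bio = 65.2 h with Lu-177 physical decay -> T_eff = 46.3 h
  lam <- log(2) / lu177$half_life_h + log(2) / 65.2
  tt <- c(1, 24, 48, 72)
  tac <- time_activity_curve(tt, 10 * exp(-lam * tt), "MBq", 20, 0.177)
  fit <- fit_monoexp(tac, lu177)
  expect_equal(fit$t_eff_h, 46.3, tolerance = 0.002)
  expect_equal(fit$t_bio_h, 65.2, tolerance = 0.01)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # pure physical decay: T_eff = T_phys, T_bio -> Inf
  lamp <- log(2) / lu177$half_life_h
  tac2 <- time_activity_curve(tt, 10 * exp(-lamp * tt), "MBq", 20, 0.177)
  expect_warning(fit2 <- fit_monoexp(tac2, lu177), "undefined")
  expect_equal(fit2$t_eff_h, lu177$half_life_h, tolerance = 1e-4)

  expect_error(fit_monoexp(time_activity_curve(c(1, 24), c(5, 4), "MBq")),
               "3 washout points")
  tac3 <- time_activity_curve(c(1, 24, 48, 72), c(10, 6, 7, 4), "MBq")
  expect_warning(fit_monoexp(tac3), "non-monotone")
})

test_that("noisy cohort fits average to the configured half-life", {
  curves <- gen_tac_cohort(rng_seed = 14, n_animals = 100, t_bio_cv = 0,
                           noise_cv = 0.10)
  teff <- vapply(curves, function(tc)
    suppressWarnings(fit_monoexp(tc, lu177))$t_eff_h, numeric(1))
  expect_equal(mean(teff), attr(curves, "truth")$t_eff_mean_h,
               tolerance = 0.02)
})

test_that("cumulated activity combines trapezoid and analytic tail", {
  lam <- 0.02
  tt <- c(1, 24, 48, 72)
  a0 <- 8
  tac <- time_activity_curve(tt, a0 * exp(-lam * tt), "MBq", 20, 0.177)
  fit <- fit_monoexp(tac)
  expect_equal(fit$lambda_eff_h, lam, tolerance = 1e-6)
  # against the analytic integral of the generating exponential
  exact_inf <- a0 * (exp(-lam * 1)) / lam + 0   # from t=1 (first sample) on
  expect_equal(cumulated_activity(tac, fit, Inf), exact_inf,
               tolerance = 0.02)
  exact_72 <- a0 / lam * (exp(-lam * 1) - exp(-lam * 72))
  expect_equal(cumulated_activity(tac, fit, 72), exact_72, tolerance = 0.02)
  # truncation before the last sample: trapezoid only
  expect_lt(cumulated_activity(tac, fit, 48),
            cumulated_activity(tac, fit, 72))
  # zero activity integrates to zero (no fit needed on the trapezoid path)
  tac0 <- time_activity_curve(tt, rep(0, 4), "MBq", 20, 0.177)
  expect_equal(cumulated_activity(tac0, fit, 72), 0)
})

test_that("percent-ID curves convert through the injected activity", {
  tac <- time_activity_curve(c(1, 24), c(50, 36), "pct_id_per_mL",
                             injected_MBq = 20, volume_mL = 0.177)
  expect_equal(mrtdose:::tac_activity_MBq(tac),
               c(50, 36) / 100 * 20 * 0.177)
})

test_that("sphere dose has correct limits and matches the phi oracle", {
  # equilibrium: radius far beyond the electron range
  big <- sphere_absorbed_dose(1, 4.2e3, density_g_mL = 1, nuclide = lu177,
                              n_histories = 2e4, rng_seed = 3)
  expect_equal(big$phi_e, 1, tolerance = 0.02)
  expected <- 1e6 * 3600 * lu177$mean_electron_energy * 1.602176634e-13 / 1e-3
  expect_equal(big$dose_Gy, expected, tolerance = 0.02)

  # vanishing sphere: phi -> 0
  tiny <- sphere_absorbed_dose(1, 1e-9, density_g_mL = 1, nuclide = lu177,
                               n_histories = 2e4, rng_seed = 3)
  expect_lt(tiny$phi_e, 0.05)

  # monotone phi(R)
  vols <- c(0.01, 0.177, 2, 50)
  phis <- vapply(vols, function(v)
    sphere_absorbed_dose(1, v, nuclide = lu177, n_histories = 3e4,
                         rng_seed = 44)$phi_e, numeric(1))
  expect_true(all(diff(phis) > 0))

  # the reported mean tumor volume, against the deterministic oracle
  s177 <- sphere_absorbed_dose(1, 0.177, density_g_mL = 1.03,
                               nuclide = lu177, n_histories = 5e4,
                               rng_seed = 19)
  r_um <- (3 * 0.177 / (4 * pi))^(1 / 3) * 1e4
  phi_oracle <- oracle_sphere_phi(r_um * 1.03, lu177)  # density-scaled
  expect_equal(s177$phi_e, phi_oracle, tolerance = 0.05)
  expect_error(sphere_absorbed_dose(1, 0.1, density_g_mL = -1,
                                    nuclide = lu177), "density")
})

test_that("an end-to-end synthetic cohort lands at order 10 Gy over 72 h", {
  curves <- gen_tac_cohort(rng_seed = 2, n_animals = 5)
  doses <- vapply(curves, function(tc) {
    fit <- suppressWarnings(fit_monoexp(tc, lu177))  # noisy washouts
    at <- cumulated_activity(tc, fit, 72)
    sphere_absorbed_dose(at / tc$volume_mL, tc$volume_mL, nuclide = lu177,
                         n_histories = 1e4, rng_seed = 6)$dose_Gy
  }, numeric(1))
  # plausibility band only: same order as the reported 12.9 +/- 3.4 Gy
  expect_true(all(doses > 2 & doses < 60))
})

test_that("worked-example conversions reproduce the printed figures", {
  expect_equal(peptide_mass_ug(20, 86), 0.33, tolerance = 0.02)
  expect_equal(specific_activity_MBq_per_ug(86), 60, tolerance = 0.01)
})
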