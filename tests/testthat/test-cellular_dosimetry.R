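test_that("CSDA electron range matches the tabulated anchors", {
  expect_equal(electron_range(0.5), 1.8e3, tolerance = 0.05)
  expect_equal(electron_range(0.01), 2.5, tolerance = 0.05)
  grid <- seq(0.02, 1.8, length.out = 40)
  expect_true(all(diff(electron_range(grid)) > 0))   # strictly increasing
  expect_error(electron_range(0), "positive")
  expect_error(electron_range(-1), "positive")
  # residual-energy inversion is consistent with the forward table
  e <- c(0.05, 0.2, 0.49)
  expect_equal(mrtdose:::energy_from_range(electron_range(e)), e,
               tolerance = 1e-6)
})

test_that("S value obeys the full-local-absorption limit", {
  geo <- cell_geometry(5e4, 1e5)   # nucleus far larger than electron range
  s <- compute_svalue(geo, "nucleus", lu177, n_histories = 2e4, rng_seed = 5)
  m_kg <- 4 / 3 * pi * (5e4 * 1e-4)^3 * 1e-3
  expect_equal(s$absorbed_fraction, 1, tolerance = 0.02)
  expect_equal(s$S_Gy_per_Bq_s,
               lu177$mean_electron_energy * 1.602176634e-13 / m_kg,
               tolerance = 0.02)
})

test_that("degenerate inputs error or vanish as specified", {
  geo <- cell_geometry()
  expect_equal(compute_svalue(geo, "nucleus", zero_yield_nuclide(),
                              1e4, 1)$S_Gy_per_Bq_s, 0)
  expect_error(compute_svalue(geo, "mitochondria", lu177, 1e4), "unknown compartment")
  expect_error(compute_svalue(geo, "nucleus", lu177, n_histories = 100),
               "too small")
  expect_error(cell_geometry(10, 5), "r_nucleus < r_cell")
})

test_that("fixed seed gives bit-identical S values and SE scales sanely", {
  geo <- cell_geometry()
  s1 <- compute_svalue(geo, "cytoplasm", lu177, 2e4, rng_seed = 77)
  s2 <- compute_svalue(geo, "cytoplasm", lu177, 2e4, rng_seed = 77)
  expect_identical(s1$S_Gy_per_Bq_s, s2$S_Gy_per_Bq_s)
  expect_gt(s1$se, 0)
})

test_that("source-distance monotonicity holds within MC error", {
  s <- svalue_set(cell_geometry(), lu177, n_histories = 5e4, rng_seed = 42)
  v <- s$values
  tol_nn <- 3 * sqrt(v$nucleus$se^2 + v$cytoplasm$se^2)
  tol_cy <- 3 * sqrt(v$cytoplasm$se^2 + v$membrane$se^2)
  expect_gt(v$nucleus$S_Gy_per_Bq_s, v$cytoplasm$S_Gy_per_Bq_s - tol_nn)
  expect_gt(v$cytoplasm$S_Gy_per_Bq_s, v$membrane$S_Gy_per_Bq_s - tol_cy)
  for (vv in v) {
    expect_gte(vv$absorbed_fraction, 0)
    expect_lte(vv$absorbed_fraction, 1)
  }
})

test_that("MC S value agrees with the deterministic integration oracle", {
  # the canonical 5/10 um geometry plus two random small geometries
  set.seed(9)
  geoms <- c(list(cell_geometry(5, 10)),
             lapply(1:2, function(i) {
               rn <- runif(1, 2.5, 6); cell_geometry(rn, rn + runif(1, 2, 6))
             }))
  for (g in geoms) {
    for (src in c("nucleus", "cytoplasm")) {
      mc <- compute_svalue(g, src, lu177, n_histories = 4e4, rng_seed = 33)
      or <- oracle_svalue(g, src, lu177)
      expect_lt(abs(mc$S_Gy_per_Bq_s - or),
                3 * mc$se + 0.02 * or)  # 3 SE plus oracle grid tolerance
    }
  }
})

test_that("reciprocity holds approximately for nucleus/cytoplasm", {
  g <- cell_geometry(5, 10)
  n <- 2e5
  set.seed(12)
  # S(N<-Cy) via package; S(Cy<-N) assembled from sphere-chord deposits
  s_ncy <- compute_svalue(g, "cytoplasm", lu177, n, rng_seed = 12)
  r <- mrtdose:::sample_shell_radius(n, 0, g$r_nucleus_um)
  mu <- runif(n, -1, 1)
  e <- sample_electron_emission(lu177, n, rng_seed = 13)
  dep_cell <- mrtdose:::chord_deposit(r, mu, e, g$r_cell_um)
  dep_nuc <- mrtdose:::chord_deposit(r, mu, e, g$r_nucleus_um)
  m_cy <- 4 / 3 * pi * ((g$r_cell_um * 1e-4)^3 - (g$r_nucleus_um * 1e-4)^3) * 1e-3
  s_cyn <- electron_yield(lu177) * mean(dep_cell - dep_nuc) *
    1.602176634e-13 / m_cy
  m_n <- mrtdose:::nucleus_mass_kg(g)
  expect_equal(m_n * s_ncy$S_Gy_per_Bq_s, m_cy * s_cyn, tolerance = 0.05)
})

test_that("suspension cross-dose follows the equilibrium closed form", {
  tc0 <- compartment_timecourse(c(0, 2), c(0, 0), c(0, 0), c(0, 0),
                                medium_Bq_per_mL = 0,
                                cell_density_per_mL = 0)
  expect_equal(suspension_cross_dose(tc0, lu177, 2), 0)

  tc <- compartment_timecourse(c(0, 2), c(0, 0), c(0, 0), c(0, 0),
                               medium_Bq_per_mL = 1e6,
                               cell_density_per_mL = 0)
  expected <- 1e6 * 7200 * lu177$mean_electron_energy *
    1.602176634e-13 / 1e-3
  expect_equal(suspension_cross_dose(tc, lu177, 2), expected,
               tolerance = 1e-10)
  # linearity in concentration
  tc2 <- compartment_timecourse(c(0, 2), c(0, 0), c(0, 0), c(0, 0),
                                medium_Bq_per_mL = 2e6,
                                cell_density_per_mL = 0)
  expect_equal(suspension_cross_dose(tc2, lu177, 2),
               2 * suspension_cross_dose(tc, lu177, 2))
  expect_error(suspension_cross_dose(tc, lu177, 5), "exceeds")
})

test_that("nucleus dose = sum of Atilde x S terms plus cross-dose", {
  g <- cell_geometry()
  s <- svalue_set(g, lu177, n_histories = 2e4, rng_seed = 8)
  # paper-like split: membrane-dominant, cytoplasm 13%, nucleus < 0.1%
  a_tot <- 57e-3
  tc <- compartment_timecourse(
    c(0, 2), rep(a_tot * 0.8695, 2), rep(a_tot * 0.13, 2),
    rep(a_tot * 0.0005, 2),
    medium_Bq_per_mL = 2.5e6, cell_density_per_mL = 1e6)
  d <- nucleus_dose(tc, s, lu177, t_end_h = 2)
  expected_self <- 2 * 3600 * (
    a_tot * 0.8695 * s$values$membrane$S_Gy_per_Bq_s +
    a_tot * 0.13 * s$values$cytoplasm$S_Gy_per_Bq_s +
    a_tot * 0.0005 * s$values$nucleus$S_Gy_per_Bq_s)
  expect_equal(d$self_Gy, expected_self, tolerance = 1e-10)
  expect_equal(d$total_Gy, d$self_Gy + d$cross_Gy)
  # the membrane + cross terms dominate for this distribution
  expect_gt(d$by_source_Gy[["membrane"]] + d$cross_Gy, 0.9 * d$total_Gy)

  # additivity over source compartments
  tc_m <- compartment_timecourse(c(0, 2), rep(1, 2), c(0, 0), c(0, 0), 0, 0)
  tc_c <- compartment_timecourse(c(0, 2), c(0, 0), rep(1, 2), c(0, 0), 0, 0)
  tc_mc <- compartment_timecourse(c(0, 2), rep(1, 2), rep(1, 2), c(0, 0), 0, 0)
  expect_equal(nucleus_dose(tc_m, s, lu177, 2)$self_Gy +
                 nucleus_dose(tc_c, s, lu177, 2)$self_Gy,
               nucleus_dose(tc_mc, s, lu177, 2)$self_Gy)
  # all-zero activities
  tc_z <- compartment_timecourse(c(0, 2), c(0, 0), c(0, 0), c(0, 0), 0, 0)
  expect_equal(nucleus_dose(tc_z, s, lu177, 2)$total_Gy, 0)
})

test_that("timecourse CSV round-trips losslessly", {
  tc <- gen_uptake_timecourse(rng_seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, p)
  tc2 <- read_timecourse(p)
  expect_equal(as.data.frame(tc2), as.data.frame(tc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(tc2, "cell_density_per_mL"),
               attr(tc, "cell_density_per_mL"))
})
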