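#' Tumor time-activity curve
#'
#' Volume-of-interest activity samples from serial SPECT imaging after a
#' radiopharmaceutical administration.
#'
#' @param times_h Imaging times, hours post injection, increasing.
#' @param activity Activity in the VOI at each time, in the unit given.
#' @param unit `"MBq"` or `"pct_id_per_mL"` (percent injected dose per mL).
#' @param injected_MBq Injected activity, MBq.
#' @param volume_mL VOI volume, mL.
#' @param density_g_mL Tissue density (1.03 g/mL for soft/lymphoid tissue).
#' @return `time_activity_curve` object.
#' @export
time_activity_curve <- function(times_h, activity, unit = c("MBq",
                                "pct_id_per_mL"), injected_MBq = NA_real_,
                                volume_mL = NA_real_, density_g_mL = 1.03) {
  unit <- match.arg(unit)
  assert_that(all(diff(times_h) > 0), "times must be strictly increasing")
  assert_that(all(activity >= 0), "activity must be >= 0")
  assert_that(is.na(volume_mL) || volume_mL > 0, "volume must be positive")
  structure(list(times_h = times_h, activity = activity, unit = unit,
                 injected_MBq = injected_MBq, volume_mL = volume_mL,
                 density_g_mL = density_g_mL),
            class = "time_activity_curve")
}

# VOI activity in MBq regardless of the stored unit.
# NOTE: %ID conversions use the injected activity without decay
# correction; the convention is configurable upstream of this package.
tac_activity_MBq <- function(tac) {
  if (tac$unit == "MBq") return(tac$activity)
  tac$activity / 100 * tac$injected_MBq * tac$volume_mL
}

#' Mono-exponential washout fit
#'
#' Fits A(t) = A0 exp(-lambda_eff t) to the washout phase of a tumor
#' time-activity curve by nonlinear least squares (the peak is
#' auto-detected as the maximum sample; samples at and after it form the
#' washout phase). Returns the effective half-life and, given the nuclide's
#' physical half-life, the biological half-life via
#' 1/T_eff = 1/T_phys + 1/T_bio.
#'
#' Measurement noise on activity quantification is typically
#' multiplicative; with `error_model = "lognormal"` the fit is ordinary
#' least squares on log activity (the maximum-likelihood estimator under
#' lognormal noise), while the default `"gaussian"` uses nonlinear least
#' squares on the original scale.
#'
#' @param tac `time_activity_curve` (non-decay-corrected activities).
#' @param nuclide Optional `nuclide_data` supplying T_phys.
#' @param error_model `"gaussian"` (nls on the activity scale) or
#'   `"lognormal"` (OLS on log activity).
#' @return `tac_fit`: `A0` (at t = 0), `lambda_eff_h`, `t_eff_h`,
#'   `t_phys_h`, `t_bio_h`, `r_squared`, `residuals`, `washout_idx`.
#' @export
fit_monoexp <- function(tac, nuclide = NULL,
                        error_model = c("gaussian", "lognormal")) {
  error_model <- match.arg(error_model)
  a <- tac_activity_MBq(tac)
  peak <- which.max(a)
  idx <- peak:length(a)
  assert_that(length(idx) >= 3, "need >= 3 washout points past the peak")
  tt <- tac$times_h[idx]; aa <- a[idx]
  if (any(diff(aa) > 0))
    warn_mrt("non-monotone washout; fit proceeds")
  assert_that(all(aa > 0), "washout activities must be positive to fit")
  # log-linear start, then nls on the original scale
  st <- stats::lm(log(aa) ~ tt)
  start <- list(A0 = exp(unname(stats::coef(st)[1])),
                lam = max(-unname(stats::coef(st)[2]), 1e-6))
  resid0 <- aa - start$A0 * exp(-start$lam * tt)
  if (error_model == "lognormal" ||
      max(abs(resid0)) < 1e-8 * start$A0) {
    # log-OLS is the lognormal MLE (and exact on noiseless curves)
    A0 <- start$A0; lam <- start$lam; resid <- resid0
  } else {
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(aa ~ A0 * exp(-lam * tt), start = start,
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      A0 <- start$A0; lam <- start$lam
      resid <- resid0
    } else {
      cf <- stats::coef(fit)
      A0 <- unname(cf["A0"]); lam <- unname(cf["lam"])
      resid <- stats::residuals(fit)
    }
  }
  t_eff <- log(2) / lam
  t_phys <- if (!is.null(nuclide)) nuclide$half_life_h else NA_real_
  t_bio <- if (!is.na(t_phys)) {
    inv <- 1 / t_eff - 1 / t_phys
    if (inv <= 0) {
      warn_mrt("fitted T_eff >= T_phys; biological half-life undefined (Inf)")
      Inf
    } else 1 / inv
  } else NA_real_
  r2 <- 1 - sum(resid^2) / sum((aa - mean(aa))^2)
  structure(list(A0 = A0, lambda_eff_h = lam, t_eff_h = t_eff,
                 t_phys_h = t_phys, t_bio_h = t_bio, r_squared = r2,
                 residuals = resid, washout_idx = idx, tac = tac),
            class = "tac_fit")
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf("<tac_fit> T_eff = %.2f h (lambda = %.4g /h), A0 = %.3g, R2 = %.4f\n",
              x$t_eff_h, x$lambda_eff_h, x$A0, x$r_squared))
  invisible(x)
}

#' Cumulated activity
#'
#' Time-integrated activity: trapezoid over the observed samples plus an
#' analytic mono-exponential tail from the last sample to `t_end_h`
#' (A_last / lambda_eff for t_end = Inf). A `t_end_h` before the last
#' sample gives the truncated trapezoid only.
#'
#' @param tac `time_activity_curve`.
#' @param fit `tac_fit` from [fit_monoexp()].
#' @param t_end_h Integration end, hours (default `Inf`).
#' @return Cumulated activity in MBq h.
#' @export
cumulated_activity <- function(tac, fit, t_end_h = Inf) {
  a <- tac_activity_MBq(tac)
  tt <- tac$times_h
  t_last <- tt[length(tt)]
  if (t_end_h <= t_last) {
    keep <- tt <= t_end_h
    t2 <- tt[keep]; a2 <- a[keep]
    if (t_end_h > t2[length(t2)]) {
      a2 <- c(a2, stats::approx(tt, a, xout = t_end_h)$y)
      t2 <- c(t2, t_end_h)
    }
    return(trapz(t2, a2))
  }
  lam <- fit$lambda_eff_h
  a_last <- a[length(a)]
  tail <- if (is.infinite(t_end_h)) a_last / lam else
    a_last / lam * (1 - exp(-lam * (t_end_h - t_last)))
  trapz(tt, a) + tail
}

# electron absorbed fraction of a uniform-activity sphere of radius R (um),
# straight-line CSDA Monte Carlo (shared with the cellular transport)
sphere_absorbed_fraction <- function(radius_um, nuclide, n_histories = 2e4,
                                     rng_seed = NULL, density_g_cm3 = 1) {
  with_seed(rng_seed, {
    n <- as.integer(n_histories)
    r <- sample_shell_radius(n, 0, radius_um)
    mu <- stats::runif(n, -1, 1)
    e <- sample_electron_emission(nuclide, n)
    # path length to sphere exit
    L <- -r * mu + sqrt(radius_um^2 - r^2 * (1 - mu^2))
    dep <- e - residual_energy(e, L, density_g_cm3)
    phi <- mean(dep) / mean(e)
    se <- stats::sd(dep / mean(e)) / sqrt(n)
    list(phi = phi, se = se)
  })
}

# mass energy-absorption coefficient of water (cm2/g), NIST anchors,
# used only by the optional crude photon self-dose term
muen_water <- function(energy_keV) {
  e <- c(20, 30, 40, 50, 60, 80, 100, 150, 200, 300, 500)
  m <- c(0.5503, 0.1557, 0.0695, 0.0424, 0.0320, 0.0262, 0.0256, 0.0277,
         0.0297, 0.0319, 0.0330)
  exp(stats::approx(log(e), log(m), xout = log(pmin(pmax(energy_keV, 20),
                                                    500)), rule = 2)$y)
}

#' Sphere-model absorbed dose
#'
#' Absorbed dose to a uniform sphere of activity (the standard sphere
#' model for tumor dosimetry, here a Monte-Carlo re-implementation):
#' electron absorbed fraction phi_e(R) from straight-line CSDA transport,
#' dose = A_tilde_conc x (phi_e Delta_e [+ phi_gamma Delta_gamma]) / rho.
#' The photon term uses a crude mean-chord mu_en approximation
#' (phi_gamma = 1 - exp(-mu_en rho c_bar)) and is OFF by default: at
#' mouse-tumor scale the electron dose dominates.
#'
#' @param cumulated_MBq_h_per_mL Cumulated activity concentration.
#' @param volume_mL Sphere volume, mL.
#' @param density_g_mL Density (1.03 for lymphoid-like soft tissue).
#' @param nuclide `nuclide_data`.
#' @param n_histories Monte-Carlo histories for phi_e.
#' @param rng_seed Optional seed.
#' @param include_photons Add the crude photon self-dose term.
#' @param fit Optional `tac_fit`; if given, dose rates at the sampled
#'   times are reported from the fitted A(t).
#' @return `sphere_dose` list: `dose_Gy`, `phi_e`, `phi_e_se`,
#'   `radius_mm`, `photon_dose_Gy`, optional `dose_rate_Gy_per_h` table.
#' @export
sphere_absorbed_dose <- function(cumulated_MBq_h_per_mL, volume_mL,
                                 density_g_mL = 1.03, nuclide,
                                 n_histories = 2e4, rng_seed = NULL,
                                 include_photons = FALSE, fit = NULL) {
  assert_that(density_g_mL > 0, "nonphysical density")
  assert_that(volume_mL > 0, "volume must be positive")
  radius_um <- (3 * volume_mL / (4 * pi))^(1 / 3) * 1e4
  af <- sphere_absorbed_fraction(radius_um, nuclide, n_histories, rng_seed,
                                 density_g_cm3 = density_g_mL)
  decays_per_mL <- cumulated_MBq_h_per_mL * 1e6 * 3600
  mass_mL_kg <- density_g_mL * 1e-3
  e_dose <- decays_per_mL * af$phi * nuclide$mean_electron_energy *
    MEV_TO_J / mass_mL_kg
  ph_dose <- 0
  if (include_photons && nrow(nuclide$photons) > 0) {
    cbar_cm <- 4 / 3 * radius_um * 1e-4
    phi_g <- 1 - exp(-muen_water(nuclide$photons$energy_keV) *
                       density_g_mL * cbar_cm)
    delta_g <- sum(nuclide$photons$energy_keV / 1000 *
                     nuclide$photons$yield * phi_g)
    ph_dose <- decays_per_mL * delta_g * MEV_TO_J / mass_mL_kg
  }
  rate <- NULL
  if (!is.null(fit)) {
    tt <- fit$tac$times_h
    a_t <- fit$A0 * exp(-fit$lambda_eff_h * tt)       # MBq in VOI
    conc <- a_t / fit$tac$volume_mL                   # MBq/mL
    rate <- data.frame(
      time_h = tt,
      dose_rate_Gy_per_h = conc * 1e6 * 3600 * af$phi *
        nuclide$mean_electron_energy * MEV_TO_J / mass_mL_kg)
  }
  structure(list(dose_Gy = e_dose + ph_dose, electron_dose_Gy = e_dose,
                 photon_dose_Gy = ph_dose, phi_e = af$phi,
                 phi_e_se = af$se, radius_mm = radius_um / 1000,
                 dose_rate = rate),
            class = "sphere_dose")
}

#' @export
print.sphere_dose <- function(x, ...) {
  cat(sprintf("<sphere_dose> %.3g Gy (phi_e = %.3f +/- %.3f, R = %.2f mm)\n",
              x$dose_Gy, x$phi_e, x$phi_e_se, x$radius_mm))
  invisible(x)
}

#' Read a time-activity-curve CSV
#'
#' Schema: `time_h` plus either `activity_MBq` or `percent_id_per_mL`;
#' header lines may carry `# injected_MBq=`, `# volume_mL=`,
#' `# density_g_mL=`.
#' @param path File path.
#' @return `time_activity_curve`.
#' @export
read_tac_csv <- function(path) {
  df <- read_table_csv(path)
  hdr <- paste(attr(df, "source_header"), collapse = " ")
  getv <- function(key, default) {
    m <- regmatches(hdr, regexec(paste0(key, "=([0-9.eE+-]+)"), hdr))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else default
  }
  if (!is.null(df$activity_MBq))
    time_activity_curve(df$time_h, df$activity_MBq, "MBq",
                        injected_MBq = getv("injected_MBq", NA),
                        volume_mL = getv("volume_mL", NA),
                        density_g_mL = getv("density_g_mL", 1.03))
  else
    time_activity_curve(df$time_h, df$percent_id_per_mL, "pct_id_per_mL",
                        injected_MBq = getv("injected_MBq", NA),
                        volume_mL = getv("volume_mL", NA),
                        density_g_mL = getv("density_g_mL", 1.03))
}

#' Worked-example unit conversions for radiolabeled peptides
#'
#' Small exact-arithmetic helpers for the standard bookkeeping around a
#' DOTATATE administration: peptide mass at a given activity and molar
#' activity, and molar-to-mass specific activity conversion.
#'
#' @param activity_MBq Administered activity, MBq.
#' @param molar_activity_MBq_per_nmol Molar activity, MBq/nmol.
#' @param mw_g_per_mol Molar mass (default: DOTATATE, 1435.6 g/mol).
#' @return Mass in micrograms / specific activity in MBq/ug.
#' @export
peptide_mass_ug <- function(activity_MBq, molar_activity_MBq_per_nmol,
                            mw_g_per_mol = DOTATATE_MW) {
  nmol <- activity_MBq / molar_activity_MBq_per_nmol
  nmol * mw_g_per_mol * 1e-3   # nmol x g/mol = ng; -> ug
}

#' @rdname peptide_mass_ug
#' @export
specific_activity_MBq_per_ug <- function(molar_activity_MBq_per_nmol,
                                         mw_g_per_mol = DOTATATE_MW) {
  molar_activity_MBq_per_nmol / (mw_g_per_mol * 1e-3)
}
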