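.mrtdose_cache <- new.env(parent = emptyenv())

csda_table <- function() {
  if (is.null(.mrtdose_cache$csda)) {
    path <- system.file("extdata", "csda_water.csv", package = "mrtdose")
    .mrtdose_cache$csda <- read_table_csv(path)
  }
  .mrtdose_cache$csda
}

#' CSDA electron range in water
#'
#' Continuous-slowing-down-approximation range of an electron in liquid
#' water, by log-log interpolation of the shipped NIST-ESTAR anchor table
#' (0.01-2 MeV). Below the lowest anchor the first log-log segment is
#' extrapolated; this only affects the last couple of micrometres of a
#' track.
#'
#' @param energy_MeV Electron kinetic energies in MeV, all in (0, 2].
#' @param density_g_cm3 Medium density; ranges scale as 1/density.
#' @return Ranges in micrometres.
#' @examples
#' electron_range(0.5)   # ~1.8e3 um
#' electron_range(0.01)  # ~2.5 um
#' @export
electron_range <- function(energy_MeV, density_g_cm3 = 1) {
  assert_that(all(energy_MeV > 0), "energy must be positive")
  assert_that(all(energy_MeV <= 2), "energy above tabulated limit (2 MeV)")
  tb <- csda_table()
  r_g_cm2 <- exp(stats::approx(log(tb$energy_MeV), log(tb$csda_g_cm2),
                               xout = log(energy_MeV), rule = 2)$y)
  # extrapolate below lowest anchor with the first segment's slope
  lo <- energy_MeV < tb$energy_MeV[1]
  if (any(lo)) {
    sl <- (log(tb$csda_g_cm2[2]) - log(tb$csda_g_cm2[1])) /
      (log(tb$energy_MeV[2]) - log(tb$energy_MeV[1]))
    r_g_cm2[lo] <- exp(log(tb$csda_g_cm2[1]) +
                         sl * (log(energy_MeV[lo]) - log(tb$energy_MeV[1])))
  }
  r_g_cm2 / density_g_cm3 * 1e4  # cm -> um at unit density
}

# inverse of electron_range(): energy (MeV) of an electron whose residual
# CSDA range is `range_um`; 0 for non-positive ranges
energy_from_range <- function(range_um, density_g_cm3 = 1) {
  tb <- csda_table()
  r_tab <- tb$csda_g_cm2 / density_g_cm3 * 1e4
  out <- numeric(length(range_um))
  pos <- range_um > 0
  if (any(pos)) {
    e <- exp(stats::approx(log(r_tab), log(tb$energy_MeV),
                           xout = log(range_um[pos]), rule = 2)$y)
    lo <- range_um[pos] < r_tab[1]
    if (any(lo)) {
      sl <- (log(tb$energy_MeV[2]) - log(tb$energy_MeV[1])) /
        (log(r_tab[2]) - log(r_tab[1]))
      e[lo] <- exp(log(tb$energy_MeV[1]) +
                     sl * (log(range_um[pos][lo]) - log(r_tab[1])))
    }
    out[pos] <- e
  }
  out
}

# residual energy after an electron of initial energy E travels path s (um)
residual_energy <- function(energy_MeV, path_um, density_g_cm3 = 1) {
  r0 <- electron_range(energy_MeV, density_g_cm3)
  energy_from_range(r0 - path_um, density_g_cm3)
}
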