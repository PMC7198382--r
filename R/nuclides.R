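#' Radionuclide physical data
#'
#' Loads the decay data shipped with the package for the radionuclides used
#' in somatostatin-receptor radionuclide therapy studies: the beta emitter
#' Lu-177 (gammas at 113 and 208 keV) and the SPECT isotope In-111 (gammas
#' at 171 and 245 keV, no beta emission). Tables are plain-text CSV under
#' `inst/extdata/nuclides/` with `# source=` provenance headers.
#'
#' @param name Nuclide identifier, one of `"Lu-177"` or `"In-111"`.
#' @return An object of class `nuclide_data` with fields
#'   `name`, `half_life_h`, `lambda_h` (decay constant, 1/h),
#'   `beta_yield` (betas per decay), `beta_spectrum` (data.frame
#'   `energy_MeV`, `density_per_MeV`, normalised to integrate to 1),
#'   `discrete_electrons` (`energy_MeV`, `yield`), `photons`
#'   (`energy_keV`, `yield`), `mean_electron_energy` (MeV per decay,
#'   the electron Delta value), and `source` (provenance strings).
#' @examples
#' lu <- load_nuclide("Lu-177")
#' lu$half_life_h        # ~159.5
#' lu$mean_electron_energy
#' @export
load_nuclide <- function(name) {
  supported <- c("Lu-177", "In-111")
  if (!is.character(name) || length(name) != 1L || !(name %in% supported))
    stop_mrt("unsupported nuclide '%s'; supported set: %s",
             as.character(name)[1], paste(supported, collapse = ", "))

  dir <- system.file("extdata", "nuclides", package = "mrtdose")
  idx <- read_table_csv(file.path(dir, "index.csv"))
  row <- idx[idx$name == name, ]
  stub <- tolower(gsub("-", "", name))

  spec_path <- file.path(dir, paste0(stub, "_beta_spectrum.csv"))
  beta_spectrum <- if (file.exists(spec_path)) read_table_csv(spec_path) else
    data.frame(energy_MeV = numeric(), density_per_MeV = numeric())
  electrons <- read_table_csv(file.path(dir, paste0(stub, "_electrons.csv")))
  photons <- read_table_csv(file.path(dir, paste0(stub, "_photons.csv")))

  beta_mean <- if (nrow(beta_spectrum) > 1L)
    trapz(beta_spectrum$energy_MeV,
          beta_spectrum$energy_MeV * beta_spectrum$density_per_MeV) else 0
  mean_e <- row$beta_yield * beta_mean +
    sum(electrons$energy_MeV * electrons$yield)

  structure(list(
    name = name,
    half_life_h = row$half_life_h,
    lambda_h = log(2) / row$half_life_h,
    beta_yield = row$beta_yield,
    beta_spectrum = beta_spectrum,
    discrete_electrons = electrons,
    photons = photons,
    mean_beta_energy = row$beta_yield * beta_mean,
    mean_electron_energy = mean_e,
    source = attr(idx, "source_header")
  ), class = "nuclide_data")
}

# read a CSV that may start with '# ...' comment header lines
read_table_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  attr(df, "source_header") <- hdr
  df
}

#' @export
print.nuclide_data <- function(x, ...) {
  cat(sprintf("<nuclide_data> %s  T1/2 = %.2f h\n", x$name, x$half_life_h))
  cat(sprintf("  beta yield %.3f /decay, mean electron energy %.4f MeV/decay\n",
              x$beta_yield, x$mean_electron_energy))
  cat(sprintf("  %d discrete electron lines, %d photon lines\n",
              nrow(x$discrete_electrons), nrow(x$photons)))
  invisible(x)
}

#' Total electron yield per decay (betas + conversion/Auger)
#' @param nuclide A `nuclide_data` object.
#' @return Electrons emitted per decay.
#' @export
electron_yield <- function(nuclide) {
  nuclide$beta_yield + sum(nuclide$discrete_electrons$yield)
}

#' Sample electron emission energies
#'
#' Draws energies from the mixed continuous (beta spectrum) + discrete
#' (conversion/Auger) electron emission distribution of a nuclide, one draw
#' per emitted electron. The continuous part is sampled by inverse-CDF on
#' the tabulated spectrum with linear interpolation.
#'
#' @param nuclide A `nuclide_data` object.
#' @param n Number of energies to draw (>= 1).
#' @param rng_seed Optional integer seed; fixed seed gives identical draws.
#' @return Numeric vector of energies in MeV.
#' @export
sample_electron_emission <- function(nuclide, n, rng_seed = NULL) {
  assert_that(n >= 1, "n must be >= 1")
  y_beta <- nuclide$beta_yield
  de <- nuclide$discrete_electrons
  y_disc <- sum(de$yield)
  if (y_beta + y_disc <= 0)
    stop_mrt("nuclide %s has no electron emissions", nuclide$name)
  with_seed(rng_seed, {
    from_beta <- stats::runif(n) < y_beta / (y_beta + y_disc)
    out <- numeric(n)
    nb <- sum(from_beta)
    if (nb > 0) out[from_beta] <- sample_beta_spectrum(nuclide$beta_spectrum, nb)
    nd <- n - nb
    if (nd > 0)
      out[!from_beta] <- sample(de$energy_MeV, nd, replace = TRUE,
                                prob = de$yield / y_disc)
    out
  })
}

# inverse-CDF sampling on a tabulated density (linear interpolation)
sample_beta_spectrum <- function(spectrum, n) {
  e <- spectrum$energy_MeV
  d <- spectrum$density_per_MeV
  if (length(e) < 2L) return(rep(e, length.out = n))
  cdf <- c(0, cumsum(diff(e) * (utils::head(d, -1) + utils::tail(d, -1)) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, e, xout = stats::runif(n), ties = "ordered")$y
}
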