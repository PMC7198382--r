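# shared fixtures: load nuclides once per test run
lu177 <- load_nuclide("Lu-177")
in111 <- load_nuclide("In-111")

# a made-up nuclide with a single discrete electron line, for degenerate
# sampling tests
mono_nuclide <- function(energy_MeV = 0.1, yield = 1) {
  structure(list(
    name = "mono", half_life_h = 10, lambda_h = log(2) / 10,
    beta_yield = 0,
    beta_spectrum = data.frame(energy_MeV = numeric(),
                               density_per_MeV = numeric()),
    discrete_electrons = data.frame(energy_MeV = energy_MeV, yield = yield),
    photons = data.frame(energy_keV = numeric(), yield = numeric()),
    mean_beta_energy = 0,
    mean_electron_energy = energy_MeV * yield,
    source = "synthetic test nuclide"
  ), class = "nuclide_data")
}

zero_yield_nuclide <- function() {
  n <- mono_nuclide()
  n$discrete_electrons <- n$discrete_electrons[0, ]
  n$mean_electron_energy <- 0
  n
}

# draw a disk into a matrix (used to build segmentation fixtures)
draw_disk <- function(m, cy, cx, r, value = 800) {
  rows <- pmax(1, floor(cy - r)):pmin(nrow(m), ceiling(cy + r))
  cols <- pmax(1, floor(cx - r)):pmin(ncol(m), ceiling(cx + r))
  d2 <- outer((rows - cy)^2, rep(1, length(cols))) +
    outer(rep(1, length(rows)), (cols - cx)^2)
  m[rows, cols][d2 <= r^2] <- value
  m
}
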