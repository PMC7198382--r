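# Independent deterministic oracles. These re-derive the quantities the
# Monte-Carlo code estimates, by fixed-grid quadrature with their own
# geometry arithmetic, and must not call the package's transport code.

# local copy of the CSDA interpolation (log-log on the shipped table)
.oracle_csda <- local({
  tb <- read.csv(text = grep("^#", readLines(
    system.file("extdata", "csda_water.csv", package = "mrtdose")),
    value = TRUE, invert = TRUE))
  # extend the table to 0.1 keV with the power law of its first segment,
  # so sub-table residual ranges do not clamp to the 10 keV anchor
  sl <- (log(tb$csda_g_cm2[2]) - log(tb$csda_g_cm2[1])) /
    (log(tb$energy_MeV[2]) - log(tb$energy_MeV[1]))
  e0 <- 1e-4
  r0 <- exp(log(tb$csda_g_cm2[1]) + sl * (log(e0) - log(tb$energy_MeV[1])))
  tb <- rbind(data.frame(energy_MeV = e0, csda_g_cm2 = r0), tb)
  list(
    range_um = function(e) exp(approx(log(tb$energy_MeV), log(tb$csda_g_cm2),
                                      xout = log(e), rule = 2)$y) * 1e4,
    energy = function(r_um) {
      out <- numeric(length(r_um))
      p <- r_um > 0
      if (any(p))
        out[p] <- exp(approx(log(tb$csda_g_cm2 * 1e4), log(tb$energy_MeV),
                             xout = log(r_um[p]), rule = 2)$y)
      out
    })
})

# emission-energy quadrature nodes: discrete lines plus a coarse
# resampling of the beta spectrum (n_beta midpoints)
oracle_energy_nodes <- function(nuclide, n_beta = 40) {
  de <- nuclide$discrete_electrons
  energies <- de$energy_MeV
  weights <- de$yield
  sp <- nuclide$beta_spectrum
  if (nrow(sp) > 1 && nuclide$beta_yield > 0) {
    emax <- max(sp$energy_MeV)
    edges <- seq(0, emax, length.out = n_beta + 1)
    mids <- (head(edges, -1) + tail(edges, -1)) / 2
    dens <- approx(sp$energy_MeV, sp$density_per_MeV, xout = mids,
                   rule = 2)$y
    w <- dens / sum(dens) * nuclide$beta_yield
    energies <- c(energies, mids)
    weights <- c(weights, w)
  }
  keep <- weights > 0
  list(e = energies[keep], w = weights[keep])
}

# energy deposited inside the sphere |x| <= a by electrons of energy E
# starting at radii r with direction cosines mu (vectorised over r, mu)
oracle_deposit <- function(r, mu, E, a) {
  disc <- a^2 - r^2 * (1 - mu^2)
  hits <- (r < a) | (disc > 0 & mu < 0)
  dep <- numeric(length(r))
  if (!any(hits)) return(dep)
  sq <- sqrt(pmax(disc[hits], 0))
  t_in <- ifelse(r[hits] < a, 0, -r[hits] * mu[hits] - sq)
  t_out <- -r[hits] * mu[hits] + sq
  R0 <- .oracle_csda$range_um(E)
  e_at <- function(s) ifelse(s >= R0, 0, .oracle_csda$energy(pmax(R0 - s, 0)))
  dep[hits] <- pmax(e_at(t_in) - e_at(t_out), 0)
  dep
}

# deterministic S(N <- source) by triple quadrature: source radius x
# direction cosine x emission energy
oracle_svalue <- function(geometry, source, nuclide,
                          n_r = 24, n_mu = 48) {
  b <- switch(source,
              nucleus = c(0, geometry$r_nucleus_um),
              cytoplasm = c(geometry$r_nucleus_um, geometry$r_cell_um),
              membrane = c(geometry$r_cell_um,
                           geometry$r_cell_um + geometry$membrane_thickness_um))
  rr <- seq(b[1] + (b[2] - b[1]) / (2 * n_r),
            b[2] - (b[2] - b[1]) / (2 * n_r), length.out = n_r)
  wr <- rr^2 / sum(rr^2)                       # uniform-in-volume density
  mus <- seq(-1 + 1 / n_mu, 1 - 1 / n_mu, length.out = n_mu)
  grid_r <- rep(rr, times = n_mu)
  grid_mu <- rep(mus, each = n_r)
  grid_w <- rep(wr, times = n_mu) / n_mu
  nodes <- oracle_energy_nodes(nuclide)
  mean_dep <- sum(vapply(seq_along(nodes$e), function(k) {
    nodes$w[k] * sum(grid_w * oracle_deposit(grid_r, grid_mu, nodes$e[k],
                                             geometry$r_nucleus_um))
  }, numeric(1)))
  m_kg <- 4 / 3 * pi * (geometry$r_nucleus_um * 1e-4)^3 *
    geometry$density_g_cm3 * 1e-3
  mean_dep * 1.602176634e-13 / m_kg            # Gy per Bq s
}

# electron absorbed fraction of a uniform sphere, radial quadrature
oracle_sphere_phi <- function(radius_um, nuclide, n_r = 40, n_mu = 60) {
  rr <- seq(radius_um / (2 * n_r), radius_um * (1 - 1 / (2 * n_r)),
            length.out = n_r)
  wr <- rr^2 / sum(rr^2)
  mus <- seq(-1 + 1 / n_mu, 1 - 1 / n_mu, length.out = n_mu)
  grid_r <- rep(rr, times = n_mu)
  grid_mu <- rep(mus, each = n_r)
  grid_w <- rep(wr, times = n_mu) / n_mu
  nodes <- oracle_energy_nodes(nuclide)
  dep <- 0; emitted <- 0
  for (k in seq_along(nodes$e)) {
    E <- nodes$e[k]
    R0 <- .oracle_csda$range_um(E)
    L <- -grid_r * grid_mu +
      sqrt(radius_um^2 - grid_r^2 * (1 - grid_mu^2))
    esc <- ifelse(L >= R0, 0, .oracle_csda$energy(pmax(R0 - L, 0)))
    dep <- dep + nodes$w[k] * sum(grid_w * (E - esc))
    emitted <- emitted + nodes$w[k] * E
  }
  dep / emitted
}
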