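#' Co-registered map pair
#'
#' Two co-registered 2-D maps over the same pixel grid — typically an
#' activity map (autoradiography or SPECT Lu-177 signal) and a damage map
#' (gamma-H2AX immunofluorescence or In-111 signal) — with a region-of-
#' interest mask.
#'
#' @param map_a,map_b Numeric matrices of identical shape.
#' @param mask Logical matrix (default: all pixels).
#' @param offset Integer `(d_row, d_col)` applied to `map_b` during
#'   registration (bookkeeping only).
#' @return `registered_pair` object.
#' @export
registered_pair <- function(map_a, map_b, mask = NULL, offset = c(0L, 0L)) {
  assert_that(all(dim(map_a) == dim(map_b)),
              "maps must have identical shape after registration")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map_a), ncol(map_a))
  assert_that(all(dim(mask) == dim(map_a)), "mask must match the map shape")
  structure(list(map_a = map_a, map_b = map_b, mask = mask,
                 offset = as.integer(offset)),
            class = "registered_pair")
}

#' Integer-pixel co-registration by cross-correlation
#'
#' Finds the integer translation of `map_b` (within `max_shift` px) that
#' maximises the Pearson correlation with `map_a` over the overlapping
#' (masked) region, and returns the registered pair together with the
#' attained correlation.
#'
#' @param map_a,map_b Numeric matrices (overlapping fields of view).
#' @param max_shift Maximum search shift, px.
#' @param mask Optional logical matrix on `map_a`'s grid.
#' @return `registered_pair` with attributes `shift` (`(d_row, d_col)`:
#'   the displacement of `map_b`'s content relative to `map_a`, i.e.
#'   `map_b[r + d_row, c + d_col]` matches `map_a[r, c]`) and
#'   `correlation`.
#' @export
coregister <- function(map_a, map_b, max_shift = 10, mask = NULL) {
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop_mrt("no registration signal: one of the maps is flat")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map_a), ncol(map_a))
  nr <- nrow(map_a); nc <- ncol(map_a)
  best <- c(cor = -Inf, dr = 0, dc = 0)
  for (dr in -max_shift:max_shift) {
    r_a <- max(1, 1 + dr):min(nr, nr + dr)
    r_b <- r_a - dr
    for (dc in -max_shift:max_shift) {
      c_a <- max(1, 1 + dc):min(nc, nc + dc)
      c_b <- c_a - dc
      m <- mask[r_a, c_a]
      va <- map_a[r_a, c_a][m]
      vb <- map_b[r_b, c_b][m]
      if (length(va) < 10 || stats::sd(va) == 0 || stats::sd(vb) == 0) next
      cc <- stats::cor(va, vb)
      if (cc > best["cor"]) best <- c(cor = cc, dr = dr, dc = dc)
    }
  }
  if (!is.finite(best["cor"]))
    stop_mrt("no registration signal: no informative overlap found")
  if (best["cor"] < 0.2)
    warn_mrt("low attained registration correlation (%.2f)", best["cor"])
  dr <- best["dr"]; dc <- best["dc"]
  b_shift <- matrix(NA_real_, nr, nc)
  r_a <- max(1, 1 + dr):min(nr, nr + dr)
  c_a <- max(1, 1 + dc):min(nc, nc + dc)
  b_shift[r_a, c_a] <- map_b[r_a - dr, c_a - dc]
  mask_out <- mask & !is.na(b_shift)
  b_shift[is.na(b_shift)] <- 0
  out <- registered_pair(map_a, b_shift, mask_out, offset = c(dr, dc))
  attr(out, "shift") <- c(d_row = unname(-dr), d_col = unname(-dc))
  attr(out, "correlation") <- unname(best["cor"])
  out
}

#' Wald-Wolfowitz runs test
#'
#' Tests a sign sequence for randomness via the number of runs. Used here
#' on regression residual signs ordered by the predictor to flag
#' non-linearity (too few runs); the reported p-value is the left-tailed
#' probability of observing as few or fewer runs, from the exact
#' combinatorial null for n <= 20 and the normal approximation with
#' continuity correction otherwise. Zero values are dropped.
#'
#' @param x Numeric vector (signs of residuals) or logical vector.
#' @return List: `runs`, `n_pos`, `n_neg`, `expected_runs`, `p_value`,
#'   `method`.
#' @export
runs_test <- function(x) {
  s <- sign(as.numeric(x))
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(runs = ifelse(n > 0, 1, 0), n_pos = n1, n_neg = n2,
                expected_runs = NA_real_, p_value = 1, method = "degenerate"))
  runs <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / n
  if (n <= 20) {
    p <- sum(vapply(2:runs, runs_pmf, numeric(1), n1 = n1, n2 = n2))
    method <- "exact"
  } else {
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    p <- stats::pnorm((runs + 0.5 - mu) / sqrt(v))
    method <- "normal approximation"
  }
  list(runs = runs, n_pos = n1, n_neg = n2, expected_runs = mu,
       p_value = min(max(p, 0), 1), method = method)
}

# exact null pmf of the number of runs for n1/n2 signs
runs_pmf <- function(r, n1, n2) {
  if (r < 2 || r > n1 + n2) return(0)
  if (r %% 2 == 0) {
    k <- r / 2
    2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / choose(n1 + n2, n1)
  } else {
    k <- (r - 1) / 2
    (choose(n1 - 1, k - 1) * choose(n2 - 1, k) +
       choose(n1 - 1, k) * choose(n2 - 1, k - 1)) / choose(n1 + n2, n1)
  }
}

#' Pixel-by-pixel density scatter with linear regression and runs test
#'
#' Erodes the mask by `edge_erosion_px` (to omit section-edge staining
#' artefacts), builds a 2-D histogram of (a, b) pixel pairs, regresses b on
#' a by ordinary least squares, and applies the runs test to the residual
#' signs ordered by a as a linearity check.
#'
#' @param pair `registered_pair`.
#' @param edge_erosion_px Mask erosion radius, px.
#' @param n_bins Histogram bins per axis.
#' @return `density_scatter`: histogram (`counts`, `a_breaks`,
#'   `b_breaks`), `slope`, `intercept`, `r_squared`, `runs` (runs-test
#'   result), `n_pixels`.
#' @export
density_scatter <- function(pair, edge_erosion_px = 3, n_bins = 50) {
  m <- erode_mask(pair$mask, edge_erosion_px)
  assert_that(sum(m) >= 10, "fewer than 10 masked pixels after erosion")
  a <- pair$map_a[m]; b <- pair$map_b[m]
  ab <- range(a); bb <- range(b)
  if (diff(ab) == 0) ab <- ab + c(-0.5, 0.5)
  if (diff(bb) == 0) bb <- bb + c(-0.5, 0.5)
  a_breaks <- seq(ab[1], ab[2], length.out = n_bins + 1)
  b_breaks <- seq(bb[1], bb[2], length.out = n_bins + 1)
  ia <- pmin(findInterval(a, a_breaks, rightmost.closed = TRUE), n_bins)
  ib <- pmin(findInterval(b, b_breaks, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(ia, ib)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  fit <- stats::lm(b ~ a)
  ord <- order(a)
  rt <- runs_test(stats::residuals(fit)[ord])
  r2 <- if (stats::sd(b) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)   # exact fits warn

  structure(list(counts = counts, a_breaks = a_breaks, b_breaks = b_breaks,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, runs = rt, n_pixels = length(a)),
            class = "density_scatter")
}

#' @export
print.density_scatter <- function(x, ...) {
  cat(sprintf("<density_scatter> n = %d px, slope = %.4g, R2 = %.4f, runs p = %.4g\n",
              x$n_pixels, x$slope, x$r_squared, x$runs$p_value))
  invisible(x)
}

#' Voxel-binned correlation and linear-range detection
#'
#' Partitions masked voxels into equal-width bins of `map_a` (half-open
#' `[lo, hi)` intervals, right-closed top bin), reports mean +/- SD of
#' `map_b` per bin, and determines the largest lower sub-range of bins
#' over which a linear fit of b on a passes the runs test (residual signs
#' ordered by a, `p >= alpha`). This mirrors the voxel-collection analysis
#' of dual-isotope tumor images, where the damage signal rises linearly
#' with the Lu-177 signal up to a saturation point.
#'
#' @param pair `registered_pair`.
#' @param n_bins Number of bins (>= 3).
#' @param alpha Runs-test significance level for the linearity scan.
#' @return `voxel_bin_report`: `bins` data.frame (`lo, hi, n, mean_b,
#'   sd_b`), `linear_range_max` (upper `map_a` bound of the linear range),
#'   `linear_bins`, `slope`, `r_squared`, `runs_p`.
#' @export
voxel_bin_analysis <- function(pair, n_bins = 10, alpha = 0.05) {
  assert_that(n_bins >= 3, "need n_bins >= 3")
  a <- pair$map_a[pair$mask]; b <- pair$map_b[pair$mask]
  br <- seq(min(a), max(a), length.out = n_bins + 1)
  bin <- pmin(findInterval(a, br, rightmost.closed = TRUE), n_bins)
  empty <- setdiff(seq_len(n_bins), unique(bin))
  if (length(empty)) {
    # merge empty bins with their left neighbour by dropping the break
    message(sprintf("merging %d empty bin(s) with neighbours", length(empty)))
    br <- br[-pmax(empty, 2)]
    n_bins <- length(br) - 1
    bin <- pmin(findInterval(a, br, rightmost.closed = TRUE), n_bins)
  }
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(k) {
    v <- b[bin == k]
    data.frame(lo = br[k], hi = br[k + 1], n = length(v),
               mean_b = mean(v), sd_b = stats::sd(v))
  }))
  lin <- NULL
  for (k in n_bins:3) {
    sel <- bin <= k
    aa <- a[sel]; bbv <- b[sel]
    fit <- stats::lm(bbv ~ aa)
    rt <- runs_test(stats::residuals(fit)[order(aa)])
    if (rt$p_value >= alpha || k == 3) {
      r2 <- if (stats::sd(bbv) == 0) 0 else
        suppressWarnings(summary(fit)$r.squared)   # exact fits warn
      lin <- list(k = k, slope = unname(stats::coef(fit)[2]),
                  r2 = r2, p = rt$p_value)
      break
    }
  }
  structure(list(bins = bins, linear_range_max = br[lin$k + 1],
                 linear_bins = lin$k, slope = lin$slope,
                 r_squared = lin$r2, runs_p = lin$p, breaks = br),
            class = "voxel_bin_report")
}

#' @export
print.voxel_bin_report <- function(x, ...) {
  cat(sprintf("<voxel_bin_report> %d bins; linear up to %.3g (%d bins, slope %.3g, R2 %.4f, runs p %.3g)\n",
              nrow(x$bins), x$linear_range_max, x$linear_bins, x$slope,
              x$r_squared, x$runs_p))
  invisible(x)
}
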