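# Matrix-based image primitives. Images are plain numeric matrices indexed
# (row, col), 0-based coordinates in all user-facing outputs.

#' Otsu threshold of an intensity image
#' @param x Numeric matrix (or vector) of intensities.
#' @param n_breaks Histogram resolution.
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_breaks = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- graphics::hist(v, breaks = seq(r[1], r[2], length.out = n_breaks + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# label 4- or 8-connected foreground components; 0 = background
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  add_edge <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    i2 <- (c[ok] + dc - 1L) * nr + (r[ok] + dr)
    keep <- mask[i2]
    cbind(pos[idx[ok][keep]], pos[i2[keep]])
  }
  edges[[1]] <- add_edge(1L, 0L)
  edges[[2]] <- add_edge(0L, 1L)
  if (connectivity == 8) {
    edges[[3]] <- add_edge(1L, 1L)
    edges[[4]] <- add_edge(1L, -1L)
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(rbind(em, cbind(seq_along(idx),
                                                   seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  lab[idx] <- as.integer(comp)
  lab
}

# fill holes: background components not touching the border become foreground
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

# chamfer (3-4) distance transform to the nearest background pixel,
# in units of ~pixel (divided by 3); vectorised row sweeps
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- 3 * (nr + nc) + 10
  d <- matrix(0, nr, nc)
  d[mask] <- big
  run_min <- function(v, step) {  # v[j] := min_k<=j (v[k] + step (j-k))
    j <- seq_along(v)
    cummin(v - step * j) + step * j
  }
  for (i in seq_len(nr)) {
    up <- if (i > 1) d[i - 1, ] else rep(big, nc)
    diag1 <- c(big, up[-nc]) + 4
    diag2 <- c(up[-1], big) + 4
    d[i, ] <- pmin(d[i, ], up + 3, diag1, diag2)
    d[i, ] <- run_min(d[i, ], 3)
    d[i, ] <- rev(run_min(rev(d[i, ]), 3))
  }
  for (i in rev(seq_len(nr))) {
    dn <- if (i < nr) d[i + 1, ] else rep(big, nc)
    diag1 <- c(big, dn[-nc]) + 4
    diag2 <- c(dn[-1], big) + 4
    d[i, ] <- pmin(d[i, ], dn + 3, diag1, diag2)
    d[i, ] <- run_min(d[i, ], 3)
    d[i, ] <- rev(run_min(rev(d[i, ]), 3))
  }
  d / 3
}

# 2-D FFT convolution with a centred kernel, replicate-free zero padding
convolve2d <- function(x, kernel) {
  nr <- nrow(x) + nrow(kernel) - 1
  nc <- ncol(x) + ncol(kernel) - 1
  xp <- matrix(0, nr, nc); xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  kp <- matrix(0, nr, nc); kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  conv <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    (nr * nc)
  ro <- (nrow(kernel) - 1) %/% 2
  co <- (ncol(kernel) - 1) %/% 2
  conv[ro + seq_len(nrow(x)), co + seq_len(ncol(x))]
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  ax <- seq(-radius, radius)
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# scale-normalised negative Laplacian-of-Gaussian kernel (bright blobs ->
# positive response)
log_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  ax <- seq(-radius, radius)
  r2 <- outer(ax^2, ax^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  k <- (2 - r2 / sigma^2) * g       # -Laplacian: bright blobs -> positive
  k <- k - mean(k)                  # zero DC response
  k / (2 * pi * sigma^4) * sigma^2  # scale-normalised (sigma^2 * -LoG)
}

# logical matrix of strict 8-neighbourhood local maxima
local_maxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- x
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
    res <- res & (x > nb)
  }
  res
}

# binary erosion by a disk of radius r (chamfer-distance based); the
# image border counts as background, so full masks erode at the edges
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  padded <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  d <- distance_transform(padded)
  d[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] > r
}

#' Plain-text image round-trip
#'
#' The package's on-disk image format: a CSV of pixel values preceded by a
#' `# mrtdose-map nrow=<r> ncol=<c>` header line. Lossless for the numeric
#' matrices the package works with (the offline toolchain has no TIFF
#' codec, so micrographs and activity maps travel in this text format).
#'
#' @param x Numeric matrix.
#' @param path File path.
#' @return `read_map` returns the matrix.
#' @export
write_map <- function(x, path) {
  con <- file(path, "w")
  writeLines(sprintf("# mrtdose-map nrow=%d ncol=%d", nrow(x), ncol(x)), con)
  utils::write.table(x, con, row.names = FALSE, col.names = FALSE, sep = ",")
  close(con)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  as.matrix(utils::read.table(text = body, sep = ","))
}
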