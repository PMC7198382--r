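#' Two-channel fluorescence micrograph
#'
#' In-memory container for a nucleus-stain channel (e.g. DAPI) and a
#' damage-focus channel (e.g. gamma-H2AX immunofluorescence), as numeric
#' matrices of equal shape. Pixel coordinates reported downstream are
#' 0-based `(row, col)`.
#'
#' @param nucleus,foci Numeric matrices, same dimensions, non-negative.
#' @param pixel_size_um Physical pixel size, um/px (optional).
#' @param condition,time_h Experimental metadata carried into results.
#' @return `micrograph` object.
#' @export
micrograph <- function(nucleus, foci, pixel_size_um = NA_real_,
                       condition = NA_character_, time_h = NA_real_) {
  assert_that(is.matrix(nucleus) && is.matrix(foci), "channels must be matrices")
  assert_that(all(dim(nucleus) == dim(foci)),
              "channels must have identical shape")
  assert_that(all(nucleus >= 0) && all(foci >= 0),
              "intensities must be non-negative")
  structure(list(nucleus = nucleus, foci = foci,
                 pixel_size_um = pixel_size_um,
                 condition = condition, time_h = time_h),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, condition=%s, t=%s h\n",
              nrow(x$nucleus), ncol(x$nucleus), x$condition,
              format(x$time_h)))
  invisible(x)
}

#' Segment nuclei in the nucleus channel
#'
#' Global Otsu threshold, hole filling, connected-component labelling and
#' distance-transform seeded splitting of touching nuclei (seeds = local
#' maxima of the smoothed distance transform; pixels are assigned to the
#' nearest seed). Objects below `min_area` px are removed.
#'
#' @param img `micrograph`.
#' @param min_area Minimum object area, px.
#' @param split_touching Split touching nuclei via distance-transform seeds.
#' @return Integer label matrix (0 = background, 1..K = nuclei).
#' @export
segment_nuclei <- function(img, min_area = 50, split_touching = TRUE) {
  ch <- img$nucleus
  if (diff(range(ch)) == 0) {
    warn_mrt("blank nucleus channel; no nuclei found")
    return(matrix(0L, nrow(ch), ncol(ch)))
  }
  thr <- otsu_threshold(ch)
  mask <- fill_holes(ch > thr)
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) == 0) {
    warn_mrt("no foreground objects after thresholding")
    return(lab)
  }
  if (split_touching) lab <- split_by_distance(lab)
  # area filter + sequential relabel
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# seeded splitting of merged components on the smoothed distance transform
split_by_distance <- function(lab) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  next_id <- 0L
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (length(idx) == 0) next
    # work on the component's bounding box (pad 1 px) for speed
    ir <- ((idx - 1) %% nrow(lab)) + 1
    ic <- ((idx - 1) %/% nrow(lab)) + 1
    rb <- max(1, min(ir) - 1):min(nrow(lab), max(ir) + 1)
    cb <- max(1, min(ic) - 1):min(ncol(lab), max(ic) + 1)
    comp <- matrix(FALSE, length(rb), length(cb))
    comp[cbind(ir - rb[1] + 1, ic - cb[1] + 1)] <- TRUE
    dt <- distance_transform(comp)
    dts <- convolve2d(dt, gaussian_kernel(2))
    peaks_loc <- which(local_maxima(dts) & comp & dt > 0.5 * max(dt))
    pr <- ((peaks_loc - 1) %% length(rb)) + rb[1]
    pc <- ((peaks_loc - 1) %/% length(rb)) + cb[1]
    peaks <- (pc - 1) * nrow(lab) + pr
    if (length(peaks) > 1) {
      # merge seeds closer than ~the object's inscribed radius
      ord <- order(dts[peaks_loc], decreasing = TRUE)
      sel <- integer(0)
      min_d <- max(3, 0.9 * max(dt))
      for (i in ord) {
        if (!length(sel) ||
            min(sqrt((pr[i] - pr[sel])^2 + (pc[i] - pc[sel])^2)) > min_d)
          sel <- c(sel, i)
      }
      peaks <- peaks[sel]; pr <- pr[sel]; pc <- pc[sel]
    }
    if (length(peaks) <= 1) {
      next_id <- next_id + 1L
      out[idx] <- next_id
    } else {
      r <- ((idx - 1) %% nrow(lab)) + 1
      c <- ((idx - 1) %/% nrow(lab)) + 1
      d2 <- outer(r, pr, function(a, b) (a - b)^2) +
        outer(c, pc, function(a, b) (a - b)^2)
      assign_to <- max.col(-d2)
      out[idx] <- next_id + assign_to
      next_id <- next_id + length(peaks)
    }
  }
  out
}

#' Detect gamma-H2AX foci per nucleus
#'
#' Multiscale Laplacian-of-Gaussian blob detection on the focus channel,
#' restricted to segmented nuclei. Per scale, blob candidates are strict
#' 8-neighbourhood maxima of the scale-normalised LoG response exceeding
#' `k_sigma` times the robust (MAD) noise level of that response,
#' estimated on background pixels; candidates are merged across scales by
#' greedy non-maximum suppression within `min_sep` px. Thresholds are
#' relative to the image's own noise, so detection is invariant to global
#' intensity scaling.
#'
#' In densely damaged nuclei, foci closer than the optical resolution
#' merge into single LoG blobs and maxima counting undercounts. When
#' `refine` is on (default), a fit-and-subtract (CLEAN-style) refinement
#' is run per nucleus: Gaussian amplitudes at the detected positions are
#' fitted jointly by linear least squares, the fitted model is
#' subtracted, new candidate foci are detected in the residual, and the
#' set is re-fitted; components whose fitted amplitude falls below
#' `amp_min_sd` background-noise SDs are pruned. This resolves
#' sub-resolution pairs that a pure maxima count misses, at the price of
#' assuming an approximately Gaussian focus profile.
#'
#' Nuclei with pan-nuclear staining (late-stage apoptosis) are flagged
#' and carry no focus count: a nucleus is pan-nuclear when more than
#' `pan_fraction` of its area is above the focus-intensity threshold
#' *and* the staining is uniform (median elevation above background
#' exceeding `pan_contrast` times the nucleus-internal MAD — punctate
#' foci patterns have high internal contrast and fail this conjunct).
#'
#' @param img `micrograph`.
#' @param labels Label matrix from [segment_nuclei()].
#' @param scales LoG sigmas, px.
#' @param k_sigma Detection threshold in noise SD units.
#' @param min_sep Non-maximum-suppression radius, px.
#' @param pan_fraction Pan-nuclear area fraction threshold.
#' @param pan_contrast Pan-nuclear uniformity threshold (median elevation
#'   / internal MAD).
#' @param refine Run the fit-and-subtract refinement for merged foci.
#' @param amp_min_sd Pruning threshold for fitted amplitudes, in units of
#'   the background noise SD.
#' @param max_refine_iter Maximum fit-subtract-redetect rounds.
#' @return data.frame of class `foci_table`: `nucleus_id, area_px,
#'   focus_count, pan_nuclear, condition, time_h`; detected focus
#'   positions (0-based) in `attr(, "foci")`.
#' @export
detect_foci <- function(img, labels, scales = c(1, 1.4, 2, 2.8),
                        k_sigma = 4, min_sep = 2.5, pan_fraction = 0.5,
                        pan_contrast = 3, refine = TRUE, amp_min_sd = 3,
                        max_refine_iter = 8) {
  f <- img$foci
  assert_that(all(dim(labels) == dim(f)), "label/image shape mismatch")
  n_nuc <- max(labels)
  ids <- seq_len(n_nuc)
  areas <- if (n_nuc > 0) tabulate(labels[labels > 0], n_nuc) else integer(0)

  bg <- labels == 0
  cand <- NULL
  if (diff(range(f)) > 0) {
    for (s in scales) {
      L <- convolve2d(f, log_kernel(s))
      sig <- if (any(bg)) stats::mad(L[bg]) else stats::mad(L)
      if (sig <= 0) sig <- stats::sd(L)
      hits <- which(local_maxima(L) & labels > 0 & L > k_sigma * sig)
      if (length(hits))
        cand <- rbind(cand, data.frame(
          idx = hits, scale = s, response = L[hits] / sig,
          response_raw = L[hits]))
    }
  }
  foci_pos <- data.frame(row0 = integer(), col0 = integer(),
                         scale = numeric(), response = numeric(),
                         nucleus_id = integer())
  counts <- integer(n_nuc)
  if (!is.null(cand) && nrow(cand) > 0) {
    r <- ((cand$idx - 1) %% nrow(f)) + 1
    c <- ((cand$idx - 1) %/% nrow(f)) + 1
    # rank by the scale-normalised response in signal units, so the
    # matched scale (not the least-noisy one) wins the position
    ord <- order(cand$response_raw, decreasing = TRUE)
    sel <- integer(0)
    for (i in ord) {
      if (!length(sel) ||
          min((r[i] - r[sel])^2 + (c[i] - c[sel])^2) > min_sep^2)
        sel <- c(sel, i)
    }
    foci_pos <- data.frame(row0 = r[sel] - 1L, col0 = c[sel] - 1L,
                           scale = cand$scale[sel],
                           response = cand$response[sel],
                           nucleus_id = labels[cand$idx[sel]])
    counts <- tabulate(foci_pos$nucleus_id, n_nuc)
  }

  # pan-nuclear flag: large bright area fraction AND uniform staining
  pan <- rep(FALSE, n_nuc)
  bg_med <- if (any(bg)) stats::median(f[bg]) else stats::median(f)
  bg_mad <- if (any(bg)) stats::mad(f[bg]) else stats::mad(f)
  if (n_nuc > 0 && diff(range(f)) > 0) {
    pan_thr <- bg_med + k_sigma * max(bg_mad, 1e-12)
    for (k in ids) {
      px <- f[labels == k]
      elev <- stats::median(px) - bg_med
      uniform <- elev > pan_contrast * max(stats::mad(px), 1e-12)
      pan[k] <- (mean(px > pan_thr) > pan_fraction) && uniform
    }
  }

  # fit-and-subtract refinement: recover sub-resolution merged foci.
  # The template width is estimated once per image from isolated blobs
  # (no neighbour within 8 px), whose detected scale tracks the true
  # focus width; dense nuclei cannot estimate it internally.
  if (refine && nrow(foci_pos) > 0) {
    noise_sd <- max(bg_mad, 1e-9)
    d2m <- outer(foci_pos$row0, foci_pos$row0, "-")^2 +
      outer(foci_pos$col0, foci_pos$col0, "-")^2
    diag(d2m) <- Inf
    iso <- apply(d2m, 1, min) > 64
    sigma_fit <- if (any(iso)) stats::median(foci_pos$scale[iso]) else NA
    refined <- lapply(ids[counts > 0 & !pan], function(k) {
      comp <- foci_pos[foci_pos$nucleus_id == k, , drop = FALSE]
      refine_nucleus(f, labels == k, comp, bg_med, noise_sd,
                     k_sigma = k_sigma, amp_min_sd = amp_min_sd,
                     max_iter = max_refine_iter, sigma_fit = sigma_fit)
    })
    keep <- !(foci_pos$nucleus_id %in% ids[counts > 0 & !pan])
    foci_pos <- rbind(foci_pos[keep, , drop = FALSE],
                      do.call(rbind, refined))
    counts <- if (nrow(foci_pos)) tabulate(foci_pos$nucleus_id, n_nuc)
    else integer(n_nuc)
  }
  counts_out <- ifelse(pan, NA_integer_, counts)
  if (any(pan))
    foci_pos <- foci_pos[!foci_pos$nucleus_id %in% ids[pan], , drop = FALSE]

  out <- data.frame(nucleus_id = ids, area_px = areas,
                    focus_count = counts_out, pan_nuclear = pan,
                    condition = img$condition, time_h = img$time_h)
  attr(out, "foci") <- foci_pos
  class(out) <- c("foci_table", "data.frame")
  out
}

# CLEAN-style refinement within one nucleus: jointly fit Gaussian
# amplitudes at the candidate positions (ridge-stabilised linear least
# squares at the median detected scale), prune weak components, re-detect
# peaks in the residual, iterate. Returns the refined component table.
refine_nucleus <- function(f, nuc_mask, comp, bg_med, noise_sd,
                           k_sigma, amp_min_sd, max_iter, sigma_fit = NA) {
  idx <- which(nuc_mask)
  ir <- ((idx - 1) %% nrow(f)) + 1
  ic <- ((idx - 1) %/% nrow(f)) + 1
  sig <- if (is.finite(sigma_fit)) sigma_fit else stats::median(comp$scale)
  pad <- ceiling(3 * sig)
  rb <- max(1, min(ir) - pad):min(nrow(f), max(ir) + pad)
  cb <- max(1, min(ic) - pad):min(ncol(f), max(ic) + pad)
  y <- as.numeric(f[rb, cb]) - bg_med
  pr <- as.numeric(outer(rb, rep(1, length(cb))))
  pc <- as.numeric(outer(rep(1, length(rb)), cb))
  in_nuc <- matrix(FALSE, length(rb), length(cb))
  in_nuc[cbind(ir - rb[1] + 1, ic - cb[1] + 1)] <- TRUE
  cr <- comp$row0 + 1; cc <- comp$col0 + 1
  amp <- numeric(0)
  fit_prune <- function(cr, cc, sig) {
    # LS amplitudes; backward-eliminate the weakest component at a time
    # (duplicate candidates split amplitude, so joint pruning would
    # delete both); Gram matrix cached and subset across eliminations
    if (!length(cr)) return(list(cr = cr, cc = cc, a = numeric(0),
                                 model = 0 * y))
    G <- exp(-(outer(pr, cr, "-")^2 + outer(pc, cc, "-")^2) / (2 * sig^2))
    GtG <- crossprod(G)
    Gty <- drop(crossprod(G, y))
    act <- seq_along(cr)
    repeat {
      if (!length(act)) return(list(cr = numeric(0), cc = numeric(0),
                                    a = numeric(0), model = 0 * y))
      a <- drop(solve(GtG[act, act, drop = FALSE] +
                        1e-8 * diag(length(act)), Gty[act]))
      w <- which.min(a)
      if (a[w] >= amp_min_sd * noise_sd)
        return(list(cr = cr[act], cc = cc[act], a = a,
                    model = drop(G[, act, drop = FALSE] %*% a)))
      act <- act[-w]
    }
  }
  for (it in seq_len(max_iter)) {
    ft <- fit_prune(cr, cc, sig)
    cr <- ft$cr; cc <- ft$cc; amp <- ft$a
    if (!length(cr)) break
    resid <- matrix(y - ft$model, length(rb), length(cb))
    L <- convolve2d(resid, log_kernel(sig))
    sig_L <- max(stats::mad(L), 1e-12)
    peaks <- which(local_maxima(L) & in_nuc & L > k_sigma * sig_L)
    added <- FALSE
    if (length(peaks)) {
      nr_ <- ((peaks - 1) %% length(rb)) + rb[1]
      nc_ <- ((peaks - 1) %/% length(rb)) + cb[1]
      d2 <- outer(nr_, cr, "-")^2 + outer(nc_, cc, "-")^2
      new <- apply(d2, 1, min) > 1.5^2
      if (any(new)) {
        cr <- c(cr, nr_[new]); cc <- c(cc, nc_[new])
        added <- TRUE
      }
    }
    if (!added) break
  }
  if (length(cr) > length(amp)) {  # components added on the last round
    ft <- fit_prune(cr, cc, sig)
    cr <- ft$cr; cc <- ft$cc; amp <- ft$a
  }
  if (!length(cr))
    return(comp[0, , drop = FALSE])
  data.frame(row0 = cr - 1, col0 = cc - 1, scale = sig,
             response = amp / noise_sd,
             nucleus_id = comp$nucleus_id[1])
}

#' Per-condition focus statistics
#'
#' Mean +/- SD focus counts per group with a Shapiro-Wilk normality check,
#' followed by a Welch t test (two groups) or Welch ANOVA with
#' Dunnett-style comparisons against the control group (Welch t tests,
#' Holm-adjusted; a conservative stand-in for the exact Dunnett
#' procedure). Pan-nuclear nuclei are excluded; groups with fewer than
#' `min_n` nuclei are dropped with a warning.
#'
#' @param tables A `foci_table` or list of them.
#' @param group_col Grouping column (default `"condition"`).
#' @param control Control group label (default: first group).
#' @param min_n Minimum nuclei per group.
#' @return `foci_summary` list: `groups` (mean/sd/n/shapiro_p),
#'   `comparisons` (vs control), `omnibus` (Welch ANOVA, if > 2 groups).
#' @export
summarize_foci <- function(tables, group_col = "condition", control = NULL,
                           min_n = 3) {
  df <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  df <- df[!df$pan_nuclear & !is.na(df$focus_count), , drop = FALSE]
  df$group <- as.character(df[[group_col]])
  cnt <- table(df$group)
  small <- names(cnt)[cnt < min_n]
  if (length(small)) {
    warn_mrt("excluding group(s) with < %d nuclei: %s", min_n,
             paste(small, collapse = ", "))
    df <- df[!df$group %in% small, , drop = FALSE]
  }
  grps <- sort(unique(df$group))
  assert_that(length(grps) >= 2, "need >= 2 groups for comparisons")
  if (is.null(control)) control <- grps[1]

  stats_tb <- do.call(rbind, lapply(grps, function(g) {
    x <- df$focus_count[df$group == g]
    sw <- if (length(x) >= 3 && length(x) <= 5000 && stats::sd(x) > 0)
      stats::shapiro.test(x)$p.value else NA_real_
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = stats::sd(x), shapiro_p = sw)
  }))

  others <- setdiff(grps, control)
  comp <- do.call(rbind, lapply(others, function(g) {
    x <- df$focus_count[df$group == g]
    y <- df$focus_count[df$group == control]
    tt <- if (stats::sd(c(x, y)) == 0)
      list(statistic = 0, p.value = 1, estimate = c(mean(x), mean(y)))
    else stats::t.test(x, y)  # Welch by default
    data.frame(group = g, vs = control, diff = mean(x) - mean(y),
               t = unname(tt$statistic), p_value = tt$p.value)
  }))
  comp$p_adj <- stats::p.adjust(comp$p_value, "holm")

  omnibus <- if (length(grps) > 2 && stats::sd(df$focus_count) > 0)
    stats::oneway.test(focus_count ~ group, data = df) else NULL
  structure(list(groups = stats_tb, comparisons = comp, omnibus = omnibus,
                 control = control),
            class = "foci_summary")
}

#' @export
print.foci_summary <- function(x, ...) {
  cat("<foci_summary>\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("comparisons vs '%s':\n", x$control))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
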