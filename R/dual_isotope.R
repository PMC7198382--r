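#' Dual-isotope phantom series
#'
#' Calibration phantoms containing known In-111/Lu-177 activity mixtures,
#' with reconstructed VOI counts in the two isotope energy windows. This is
#' the standards-based quantification route: the scanner itself is not
#' modelled, only the linear window-count response.
#'
#' @param A_In_MBq,A_Lu_MBq True activities per tube, MBq.
#' @param counts_In_window,counts_Lu_window VOI counts per tube.
#' @param tube_id Optional identifiers.
#' @return `phantom_series` data.frame.
#' @export
phantom_series <- function(A_In_MBq, A_Lu_MBq, counts_In_window,
                           counts_Lu_window,
                           tube_id = seq_along(A_In_MBq)) {
  assert_that(all(A_In_MBq >= 0) && all(A_Lu_MBq >= 0),
              "activities must be >= 0")
  assert_that(all(counts_In_window >= 0) && all(counts_Lu_window >= 0),
              "counts must be >= 0")
  df <- data.frame(tube_id = tube_id, A_In_MBq = A_In_MBq,
                   A_Lu_MBq = A_Lu_MBq,
                   counts_In_window = round(counts_In_window),
                   counts_Lu_window = round(counts_Lu_window))
  class(df) <- c("phantom_series", "data.frame")
  df
}

#' Calibrate the two-window crosstalk matrix
#'
#' Least-squares estimate of the 2x2 sensitivity/crosstalk matrix M
#' (counts per MBq, window x isotope) from a phantom series, model
#' counts = M activities. Requires at least 3 tubes including at least
#' one single-isotope tube per isotope, and a full-rank design (tubes must
#' not all share the same In:Lu ratio).
#'
#' @param ph `phantom_series`.
#' @param max_condition Maximum admissible condition number of M.
#' @return `unmixing_calibration`: `M`, `condition_number`, per-tube
#'   `residuals` and fitted counts.
#' @export
calibrate_unmixing <- function(ph, max_condition = 1e6) {
  assert_that(nrow(ph) >= 3, "need >= 3 phantom tubes")
  if (!any(ph$A_In_MBq > 0 & ph$A_Lu_MBq == 0) ||
      !any(ph$A_Lu_MBq > 0 & ph$A_In_MBq == 0))
    warn_mrt("no single-isotope tube for one or both isotopes; crosstalk is identified only through the mixtures")
  A <- cbind(ph$A_In_MBq, ph$A_Lu_MBq)
  if (qr(A)$rank < 2)
    stop_mrt("rank-deficient phantom design: all tubes share the same In:Lu ratio; include tubes with different ratios")
  C <- cbind(ph$counts_In_window, ph$counts_Lu_window)
  # counts_w = A %*% m_w for each window w  ->  M rows by least squares
  M <- t(qr.solve(A, C))                # 2x2, rows = windows, cols = isotopes
  dimnames(M) <- list(c("In_window", "Lu_window"), c("In", "Lu"))
  fitted <- A %*% t(M)
  resid <- C - fitted
  cn <- kappa(M, exact = TRUE)
  if (any(diag(M) <= 0))
    stop_mrt("calibration produced non-positive diagonal sensitivities")
  if (cn > max_condition)
    stop_mrt("crosstalk matrix is ill-conditioned (kappa = %.3g)", cn)
  structure(list(M = M, condition_number = cn, residuals = resid,
                 fitted = fitted, n_tubes = nrow(ph)),
            class = "unmixing_calibration")
}

#' @export
print.unmixing_calibration <- function(x, ...) {
  cat("<unmixing_calibration> counts/MBq (window x isotope):\n")
  print(round(x$M, 2))
  cat(sprintf("condition number %.3g, %d tubes, residual RMS %.3g\n",
              x$condition_number, x$n_tubes, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Unmix two-window counts into isotope activities
#'
#' activities = M^-1 counts, with negative estimates clipped to zero (and
#' flagged) and standard errors propagated from Poisson counting
#' statistics: cov(A) = M^-1 diag(counts) M^-T.
#'
#' @param counts Numeric length-2 vector `(c_In_window, c_Lu_window)` or an
#'   n x 2 matrix of such rows.
#' @param cal `unmixing_calibration`.
#' @return data.frame `A_In_MBq, A_Lu_MBq, se_In, se_Lu, clipped`.
#' @export
unmix <- function(counts, cal) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  assert_that(ncol(counts) == 2, "counts must have two windows")
  if (kappa(cal$M, exact = TRUE) > 1e6)
    stop_mrt("ill-conditioned crosstalk matrix")
  Minv <- solve(cal$M)
  A <- counts %*% t(Minv)
  ses <- t(apply(counts, 1, function(cc) {
    sqrt(pmax(diag(Minv %*% diag(pmax(cc, 0)) %*% t(Minv)), 0))
  }))
  clipped <- A < 0
  A[clipped] <- 0
  data.frame(A_In_MBq = A[, 1], A_Lu_MBq = A[, 2],
             se_In = ses[, 1], se_Lu = ses[, 2],
             clipped = clipped[, 1] | clipped[, 2])
}

#' Read a phantom-series CSV
#'
#' Schema: `tube_id, A_In_MBq, A_Lu_MBq, counts_In_window,
#' counts_Lu_window`.
#' @param path File path.
#' @return `phantom_series`.
#' @export
read_phantom_csv <- function(path) {
  df <- read_table_csv(path)
  phantom_series(df$A_In_MBq, df$A_Lu_MBq, df$counts_In_window,
                 df$counts_Lu_window, df$tube_id)
}
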