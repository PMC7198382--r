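#' Clonogenic survival dataset
#'
#' Colony-formation assay data: colonies with more than 50 cells counted
#' two weeks after irradiation, per absorbed dose and replicate. Zero-dose
#' wells define the plating efficiency.
#'
#' @param dose_Gy Absorbed dose per well, Gy (0 for control wells).
#' @param colonies Colonies counted per well.
#' @param plated Cells plated per well.
#' @param modality `"EBRT"` or `"MRT"`.
#' @param condition Optional condition label.
#' @return `survival_dataset` (a data.frame).
#' @export
survival_dataset <- function(dose_Gy, colonies, plated, modality = "EBRT",
                             condition = NA_character_) {
  assert_that(all(colonies <= plated), "colonies cannot exceed cells plated")
  assert_that(all(colonies >= 0) && all(plated > 0), "counts must be valid")
  df <- data.frame(dose_Gy = dose_Gy, colonies = colonies, plated = plated,
                   modality = modality, condition = condition)
  class(df) <- c("survival_dataset", "data.frame")
  df
}

#' Surviving fraction per dose
#'
#' SF(D) = (colonies/plated) / PE, with the plating efficiency PE taken
#' from the pooled zero-dose wells and a binomial standard error.
#'
#' @param ds `survival_dataset` (must contain zero-dose wells).
#' @return data.frame `dose_Gy, sf, se, n_colonies, n_plated`.
#' @export
surviving_fraction <- function(ds) {
  z <- ds$dose_Gy == 0
  assert_that(any(z), "no zero-dose wells; plating efficiency undefined")
  pe <- sum(ds$colonies[z]) / sum(ds$plated[z])
  assert_that(pe > 0, "zero plating efficiency")
  agg <- stats::aggregate(cbind(colonies, plated) ~ dose_Gy, data = ds, sum)
  p <- agg$colonies / agg$plated
  out <- data.frame(
    dose_Gy = agg$dose_Gy,
    sf = p / pe,
    se = sqrt(pmax(p * (1 - p), 0) / agg$plated) / pe,
    n_colonies = agg$colonies,
    n_plated = agg$plated
  )
  attr(out, "plating_efficiency") <- pe
  out
}

#' Linear-quadratic fit of clonogenic survival
#'
#' Fits SF = exp(-alpha D - beta D^2) by weighted least squares on
#' ln(SF), weights = inverse variance of ln SF, with the non-negativity
#' constraints alpha, beta >= 0 enforced by an active-set reduction.
#' D90, the dose at which survival has dropped 10-fold, is the positive
#' root of alpha D + beta D^2 = ln 10.
#'
#' Zero-colony doses (SF = 0) are retained via a 0.5-colony continuity
#' correction, with a warning; other non-positive SF entries are excluded.
#'
#' @param sf_table Output of [surviving_fraction()] (or a data.frame with
#'   `dose_Gy`, `sf` and either `se` or `n_plated`).
#' @return `lq_fit` object: `alpha`, `beta`, `cov` (2x2), `d90_Gy`,
#'   fitted table and residual diagnostics.
#' @export
fit_lq <- function(sf_table) {
  tb <- sf_table[sf_table$dose_Gy >= 0, , drop = FALSE]
  if (!is.null(tb$n_colonies) && any(tb$n_colonies == 0)) {
    warn_mrt("zero-colony dose(s) present; applying 0.5-colony continuity correction")
    idx <- tb$n_colonies == 0
    pe <- attr(sf_table, "plating_efficiency") %||% 1
    tb$sf[idx] <- 0.5 / tb$n_plated[idx] / pe
    tb$se[idx] <- tb$sf[idx]  # ~100% relative error
  }
  bad <- tb$sf <= 0
  if (any(bad)) {
    warn_mrt("excluding %d non-positive SF entries", sum(bad))
    tb <- tb[!bad, , drop = FALSE]
  }
  assert_that(length(unique(tb$dose_Gy)) >= 3,
              "need >= 3 distinct doses to fit the LQ model")
  y <- log(tb$sf)
  # var(ln SF) by the delta method from the binomial SE
  v <- if (!is.null(tb$se)) (tb$se / tb$sf)^2 else rep(1, nrow(tb))
  v[!is.finite(v) | v <= 0] <- max(v[is.finite(v) & v > 0], 1)
  w <- 1 / v
  X <- cbind(-tb$dose_Gy, -tb$dose_Gy^2)

  wls <- function(cols) {
    Xc <- X[, cols, drop = FALSE]
    XtWX <- crossprod(Xc, w * Xc)
    b <- solve(XtWX, crossprod(Xc, w * y))
    list(b = drop(b), cov = solve(XtWX), cols = cols)
  }
  fit <- wls(1:2)
  ab <- c(fit$b[1], fit$b[2])
  cov <- fit$cov
  if (any(ab < 0)) {  # active-set: drop the negative parameter(s)
    ab <- pmax(ab, 0)
    keep <- which(c(fit$b[1], fit$b[2]) > 0)
    cov <- matrix(0, 2, 2)
    if (length(keep) == 1) {
      f1 <- wls(keep)
      ab <- c(0, 0); ab[keep] <- max(f1$b, 0)
      cov[keep, keep] <- f1$cov
    }
  }
  resid <- y - drop(X %*% ab)
  d90 <- lq_d90(ab[1], ab[2])
  structure(list(alpha = ab[1], beta = ab[2], cov = cov, d90_Gy = d90,
                 table = tb, residuals = resid, weights = w,
                 log_sf = y),
            class = "lq_fit")
}

# positive root of alpha D + beta D^2 = ln 10, in the numerically stable
# form 2 ln10 / (alpha + sqrt(alpha^2 + 4 beta ln10)) (no cancellation as
# beta -> 0)
lq_d90 <- function(alpha, beta) {
  if (alpha + beta <= 0) return(NA_real_)
  if (beta <= 0) return(log(10) / alpha)
  2 * log(10) / (alpha + sqrt(alpha^2 + 4 * beta * log(10)))
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("<lq_fit> alpha = %.4f /Gy, beta = %.4f /Gy^2, D90 = %.2f Gy\n",
              x$alpha, x$beta, x$d90_Gy))
  invisible(x)
}

#' Predicted surviving fraction
#' @param object `lq_fit`.
#' @param dose_Gy Doses at which to predict.
#' @param ... Unused.
#' @return data.frame `dose_Gy, sf, lnsf_se` (delta-method SE of ln SF).
#' @export
predict.lq_fit <- function(object, dose_Gy, ...) {
  lnsf <- -object$alpha * dose_Gy - object$beta * dose_Gy^2
  G <- cbind(-dose_Gy, -dose_Gy^2)
  se <- sqrt(pmax(rowSums((G %*% object$cov) * G), 0))
  data.frame(dose_Gy = dose_Gy, sf = exp(lnsf), lnsf_se = se)
}

#' Compare EBRT and MRT dose-response curves
#'
#' Predicted survival difference across a dose grid with propagated
#' confidence intervals, plus an F-test for coincidence of the two LQ
#' curves (pooled fit vs separate fits on the combined weighted residual
#' sum of squares).
#'
#' @param fit_a,fit_b `lq_fit` objects (e.g. EBRT and MRT).
#' @param dose_grid Doses at which to compare, Gy.
#' @param conf_level Confidence level for the difference CI.
#' @return `modality_comparison` list: per-dose table, F statistic, df and
#'   p-value.
#' @export
compare_modalities <- function(fit_a, fit_b, dose_grid = NULL,
                               conf_level = 0.95) {
  ra <- range(fit_a$table$dose_Gy); rb <- range(fit_b$table$dose_Gy)
  if (ra[1] > rb[2] || rb[1] > ra[2])
    warn_mrt("dose ranges of the two fits do not overlap")
  if (is.null(dose_grid))
    dose_grid <- seq(max(ra[1], rb[1]), min(ra[2], rb[2]), length.out = 25)
  pa <- predict(fit_a, dose_grid); pb <- predict(fit_b, dose_grid)
  dlog <- log(pb$sf) - log(pa$sf)
  se <- sqrt(pa$lnsf_se^2 + pb$lnsf_se^2)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(dose_Gy = dose_grid, lnsf_diff = dlog, se = se,
                    lo = dlog - zq * se, hi = dlog + zq * se)

  sse_sep <- sum(fit_a$weights * fit_a$residuals^2) +
    sum(fit_b$weights * fit_b$residuals^2)
  n <- length(fit_a$residuals) + length(fit_b$residuals)
  pool_tb <- rbind(
    data.frame(dose_Gy = fit_a$table$dose_Gy, y = fit_a$log_sf,
               w = fit_a$weights),
    data.frame(dose_Gy = fit_b$table$dose_Gy, y = fit_b$log_sf,
               w = fit_b$weights))
  Xp <- cbind(-pool_tb$dose_Gy, -pool_tb$dose_Gy^2)
  bp <- solve(crossprod(Xp, pool_tb$w * Xp), crossprod(Xp, pool_tb$w * pool_tb$y))
  sse_pool <- sum(pool_tb$w * (pool_tb$y - drop(Xp %*% bp))^2)
  df2 <- n - 4
  fstat <- ((sse_pool - sse_sep) / 2) / (sse_sep / df2)
  pval <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  structure(list(table = tab, f_statistic = fstat, df = c(2, df2),
                 p_value = pval),
            class = "modality_comparison")
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat(sprintf("<modality_comparison> F(%d,%d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Read a clonogenic-assay CSV
#'
#' Schema: `condition, dose_Gy, replicate, colonies, plated[, modality]`.
#' @param path File path.
#' @return `survival_dataset`.
#' @export
read_survival_csv <- function(path) {
  df <- read_table_csv(path)
  survival_dataset(df$dose_Gy, df$colonies, df$plated,
                   modality = if (!is.null(df$modality)) df$modality else "EBRT",
                   condition = if (!is.null(df$condition)) df$condition else NA)
}
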