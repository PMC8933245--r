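#' Per-subject spatial variance of the residual maps
#'
#' For each subject, the variance of that subject's residual map across the
#' in-mask voxels — the per-image noise estimate `var[eps]`. For weighted
#' fits the residuals are the whitened ones, which should be homoscedastic
#' when the noise model is right.
#'
#' By default the residuals are internally studentized first (divided by
#' `sqrt(1 - h_jj)`, with `h_jj` the hat-matrix diagonal): a residual map's
#' raw variance is `(1 - h_jj)` times the subject's noise variance, and in
#' weighted fits the leverage concentrates on the least noisy images, so at
#' moderate cohort sizes the uncorrected variances carry a spurious
#' design-driven dependence on image quality.
#'
#' @param fit a [fit_glm()] object (or a residual matrix, in which case no
#'   leverage correction is possible).
#' @param mask optional logical vector over voxel columns (>= 2 TRUE).
#' @param leverage_correct studentize by `sqrt(1 - h_jj)` (default `TRUE`
#'   for fit objects).
#' @return tibble: `subject` (row index), `var_eps`.
#' @export
residual_spatial_variance <- function(fit, mask = NULL, leverage_correct = TRUE) {
  res <- if (inherits(fit, "quiqir_glm")) {
    if (leverage_correct) fit$residuals / sqrt(pmax(1 - fit$leverage, 1e-12))
    else fit$residuals
  } else as.matrix(fit)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (sum(mask) < 2) abort("mask must keep at least 2 voxels.")
    res <- res[, mask, drop = FALSE]
  }
  if (ncol(res) < 2) abort("need at least 2 voxels to compute a spatial variance.")
  m <- rowMeans(res)
  tibble(subject = seq_len(nrow(res)),
         var_eps = rowSums((res - m)^2) / (ncol(res) - 1))
}

#' Polynomial heteroscedasticity R-squared
#'
#' Fits `var_eps` as a polynomial in the MDI (least squares, intercept
#' included, coefficients unconstrained in sign) and returns the coefficient
#' of determination — the fraction of the variance of image noise explained
#' by the MDI. Values near 0 indicate homoscedastic noise; large values mean
#' the noise level tracks image quality. `R^2` is defined as 0 when
#' `var_eps` has zero spread.
#'
#' @param var_eps per-subject noise estimates (see
#'   [residual_spatial_variance()]); a tibble from that function also works.
#' @param mdi per-subject MDI values.
#' @param order polynomial order (default 3).
#' @return list with `r2` and `coefficients` (intercept first).
#' @export
hetero_r2 <- function(var_eps, mdi, order = 3) {
  if (is.data.frame(var_eps)) var_eps <- var_eps$var_eps
  var_eps <- as.numeric(var_eps); mdi <- as.numeric(mdi)
  if (length(var_eps) != length(mdi)) abort("`var_eps` and `mdi` lengths differ.")
  if (length(var_eps) < order + 2) abort("need at least order + 2 observations.")
  ss_tot <- sum((var_eps - mean(var_eps))^2)
  if (ss_tot == 0) {
    return(list(r2 = 0, coefficients = c(var_eps[1], rep(0, order))))
  }
  Xp <- outer(mdi, 0:order, `^`)
  fit <- lm.fit(Xp, var_eps)
  r2 <- 1 - sum(fit$residuals^2) / ss_tot
  list(r2 = max(0, min(1, r2)),
       coefficients = setNames(fit$coefficients, paste0("mdi^", 0:order)))
}

#' Engle's ARCH test of residual heteroscedasticity at a voxel
#'
#' Lagrange-multiplier test for autoregressive conditional
#' heteroscedasticity: residuals are ordered by ascending MDI (so that
#' MDI-dependent variance manifests as volatility clustering in the series),
#' their squares are regressed on `max_lag` of their own lags, and
#' `LM = n R^2` of that auxiliary regression is referred to
#' `chi-squared(max_lag)`.
#'
#' @param residuals_at_voxel residual vector across subjects at one voxel.
#' @param mdi per-subject MDI values (defines the ordering); pass `NULL` to
#'   keep the input order.
#' @param max_lag maximum lag (default 40).
#' @return p-value.
#' @export
arch_test <- function(residuals_at_voxel, mdi = NULL, max_lag = 40) {
  r <- as.numeric(residuals_at_voxel)
  n <- length(r)
  if (n <= max_lag + 2) abort("need more subjects than max_lag + 2.")
  if (!is.null(mdi)) {
    if (length(mdi) != n) abort("`mdi` length must match the residuals.")
    r <- r[order(mdi)]
  }
  arch_lm_pvalue(r, max_lag)
}

# LM statistic and p for one pre-ordered series.
arch_lm_pvalue <- function(r, max_lag) {
  u <- r^2
  n_aux <- length(u) - max_lag
  yy <- u[(max_lag + 1):length(u)]
  Xl <- cbind(1, stats::embed(u, max_lag + 1)[, -1, drop = FALSE])
  fit <- .lm.fit(Xl, yy)
  ss_tot <- sum((yy - mean(yy))^2)
  if (ss_tot == 0) return(1)
  r2 <- 1 - sum(fit$residuals^2) / ss_tot
  pchisq(n_aux * r2, df = max_lag, lower.tail = FALSE)
}

#' Benjamini-Hochberg significance calls
#'
#' Standard step-up false-discovery-rate control at level `q` (via
#' [stats::p.adjust()]).
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical vector: which hypotheses are rejected.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  pvals <- as.numeric(pvals)
  if (length(pvals) == 0) abort("`pvals` must be non-empty.")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("`pvals` must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH") <= q
}

#' Kolmogorov-Smirnov normality check for a voxel's residuals
#'
#' Tests the (optionally standardised) residuals against the standard
#' normal.
#'
#' @param residuals_at_voxel residual vector (length >= 10).
#' @param standardize centre and scale by the sample mean/SD first. When the
#'   scale is estimated this makes the test conservative.
#' @return p-value, or `NA` with a warning for zero-variance input.
#' @export
ks_normality <- function(residuals_at_voxel, standardize = TRUE) {
  r <- as.numeric(residuals_at_voxel)
  if (length(r) < 10) abort("need at least 10 residuals.")
  if (standardize) {
    s <- stats::sd(r)
    if (s == 0) {
      warn("zero-variance residuals; KS p-value undefined.")
      return(NA_real_)
    }
    r <- (r - mean(r)) / s
  }
  suppressWarnings(ks.test(r, "pnorm"))$p.value
}

#' Full heteroscedasticity diagnostics for a fitted model
#'
#' Combines the global and voxel-level measures: per-subject residual
#' spatial variance and its polynomial R-squared against the MDI; voxel-wise
#' ARCH p-values (residuals ordered by MDI) with the FDR-significant
#' fraction; and voxel-wise KS normality p-values with their significant
#' fraction.
#'
#' @param fit a [fit_glm()] object.
#' @param mdi per-subject MDI values.
#' @param mask optional logical voxel mask.
#' @param order polynomial order for the global fit.
#' @param max_lag ARCH maximum lag; skipped (with `NA` results) when the
#'   cohort is too small for it.
#' @param q FDR level.
#' @return a `quiqir_diagnostics` object: list with `var_eps` (tibble:
#'   subject, mdi, var_eps), `r2_poly`, `poly_coefficients`, `arch_p`,
#'   `frac_arch_sig`, `ks_p`, `frac_ks_sig`, `weighted`.
#' @export
diagnose <- function(fit, mdi, mask = NULL, order = 3, max_lag = 40, q = 0.05) {
  stopifnot(inherits(fit, "quiqir_glm"))
  mdi <- as.numeric(mdi)
  if (length(mdi) != nrow(fit$residuals)) abort("`mdi` length must match subjects.")
  ve <- residual_spatial_variance(fit, mask)
  hr <- hetero_r2(ve$var_eps, mdi, order)
  res <- fit$residuals
  if (!is.null(mask)) res <- res[, as.logical(mask), drop = FALSE]
  ord <- order(mdi)
  n <- nrow(res)
  if (n > max_lag + 2) {
    arch_p <- apply(res[ord, , drop = FALSE], 2, arch_lm_pvalue, max_lag = max_lag)
    frac_arch <- mean(bh_fdr(arch_p, q))
  } else {
    arch_p <- rep(NA_real_, ncol(res))
    frac_arch <- NA_real_
  }
  ks_p <- suppressWarnings(apply(res, 2, ks_normality))
  ok <- !is.na(ks_p)
  frac_ks <- if (any(ok)) mean(bh_fdr(ks_p[ok], q)) else NA_real_
  structure(
    list(var_eps = tibble(subject = ve$subject, mdi = mdi, var_eps = ve$var_eps),
         r2_poly = hr$r2, poly_coefficients = hr$coefficients,
         arch_p = arch_p, frac_arch_sig = frac_arch,
         ks_p = ks_p, frac_ks_sig = frac_ks,
         order = order, max_lag = max_lag, q = q,
         weighted = !is.null(fit$weights)),
    class = "quiqir_diagnostics")
}

#' @export
print.quiqir_diagnostics <- function(x, ...) {
  cat(sprintf("<quiqir_diagnostics> %s fit, %d subjects, %d voxels\n",
              if (x$weighted) "weighted" else "OLS",
              nrow(x$var_eps), length(x$arch_p)))
  cat(sprintf("  polynomial R^2 (order %d) of var[eps] vs MDI: %.3f\n",
              x$order, x$r2_poly))
  if (!is.na(x$frac_arch_sig)) {
    cat(sprintf("  ARCH(%d) FDR-significant voxels: %.1f%%\n",
                x$max_lag, 100 * x$frac_arch_sig))
  }
  if (!is.na(x$frac_ks_sig)) {
    cat(sprintf("  KS-normality FDR-significant voxels: %.1f%%\n",
                100 * x$frac_ks_sig))
  }
  invisible(x)
}
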