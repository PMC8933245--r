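# broom-style accessors for the package's fitted objects

#' Tidy a REML noise-model fit
#'
#' @param x a `quiqir_reml` object.
#' @param ... unused.
#' @return tibble with one row per basis function: `power`, `lambda`
#'   (original MDI scale), `lambda_scaled` (unit-mean MDI scale).
#' @export
tidy.quiqir_reml <- function(x, ...) {
  tibble(power = x$powers,
         lambda = unname(x$lambdas),
         lambda_scaled = unname(x$lambdas_scaled))
}

#' @rdname tidy.quiqir_reml
#' @return for `glance()`: a one-row tibble with `elbo`, `iterations`,
#'   `converged`, `positivity`, `n_subjects`, `n_voxels`.
#' @export
glance.quiqir_reml <- function(x, ...) {
  tibble(elbo = x$elbo, iterations = x$iterations, converged = x$converged,
         positivity = x$positivity, n_subjects = x$n_subjects,
         n_voxels = x$n_voxels)
}

#' Tidy a mass-univariate GLM fit
#'
#' @param x a `quiqir_glm` object.
#' @param voxels optional voxel indices to keep (the full long table has
#'   p x N_voxels rows).
#' @param ... unused.
#' @return tibble: `voxel`, `term`, `estimate`.
#' @export
tidy.quiqir_glm <- function(x, voxels = NULL, ...) {
  b <- x$betas
  if (!is.null(voxels)) b <- b[, voxels, drop = FALSE]
  cols <- if (is.null(voxels)) seq_len(ncol(x$betas)) else voxels
  tibble(voxel = rep(cols, each = nrow(b)),
         term = rep(rownames(b), length(cols)),
         estimate = as.vector(b))
}

#' @rdname tidy.quiqir_glm
#' @export
glance.quiqir_glm <- function(x, ...) {
  tibble(n_subjects = nrow(x$residuals), n_voxels = ncol(x$residuals),
         dof = x$dof, weighted = !is.null(x$weights),
         mean_sigma2 = mean(x$sigma2))
}

#' Tidy a diagnostics report
#'
#' @param x a `quiqir_diagnostics` object.
#' @param ... unused.
#' @return per-subject tibble: `subject`, `mdi`, `var_eps`.
#' @export
tidy.quiqir_diagnostics <- function(x, ...) x$var_eps

#' @rdname tidy.quiqir_diagnostics
#' @export
glance.quiqir_diagnostics <- function(x, ...) {
  tibble(r2_poly = x$r2_poly, frac_arch_sig = x$frac_arch_sig,
         frac_ks_sig = x$frac_ks_sig, weighted = x$weighted,
         order = x$order, max_lag = x$max_lag)
}

#' Tidy a specificity-analysis result
#'
#' @param x a `specificity_result` object.
#' @param ... unused.
#' @return the per-replicate tibble.
#' @export
tidy.specificity_result <- function(x, ...) x$replicates

#' @rdname tidy.specificity_result
#' @export
glance.specificity_result <- function(x, ...) {
  tibble(mode = x$mode, n_replicates = x$n_replicates,
         fpr_voxel = x$fpr_voxel, fpr_cluster = x$fpr_cluster,
         alpha = x$alpha)
}
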