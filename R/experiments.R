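#' Specificity analysis I: scrambled-age false positives
#'
#' Repeatedly scrambles the age regressor (age and age squared permuted
#' jointly, so the pair stays consistent) across subjects and reruns the full
#' analysis — REML weight estimation (WLS mode), model fit, F test of the age
#' columns, and familywise-error correction. After scrambling there is no
#' true age effect, so every significant finding is a false positive; the
#' fraction of replicates with at least one is the familywise false-positive
#' rate.
#'
#' @param Y subjects x voxels matrix.
#' @param X design matrix containing `age` (and optionally `age2`) columns.
#' @param mdi per-subject MDI values.
#' @param mode "wls" (REML weights re-estimated per replicate) or "ols".
#' @param n_rep number of replicates (>= 10).
#' @param seed integer seed; replicate r uses seed + r, so extending `n_rep`
#'   reproduces earlier replicates exactly.
#' @param subsample_rule optional list `(bin_width, per_bin)`: per replicate,
#'   keep at most `per_bin` subjects per `bin_width`-year age bin.
#' @param powers MDI powers for the REML basis in WLS mode (default 3).
#' @param alpha voxel FWE level.
#' @param cluster also run cluster-level permutation inference (needs
#'   `geometry`; slower).
#' @param geometry,cft_p,n_perm_cluster cluster-inference settings.
#' @return a `specificity_result`: list with `n_replicates`, `fpr_voxel`,
#'   `fpr_cluster` (`NA` unless `cluster = TRUE`), and `replicates` (tibble:
#'   rep, seed, n_sig_voxel, positive_voxel, positive_cluster).
#' @export
specificity_scramble <- function(Y, X, mdi, mode = c("wls", "ols"),
                                 n_rep = 500L, seed = 1L,
                                 subsample_rule = NULL, powers = 3,
                                 alpha = 0.05, cluster = FALSE,
                                 geometry = NULL, cft_p = 0.001,
                                 n_perm_cluster = 200L) {
  mode <- match.arg(mode)
  Y <- check_image_matrix(Y)
  X <- check_design(X, nrow(Y))
  if (!"age" %in% colnames(X)) abort("design must contain an `age` column.")
  if (n_rep < 10) abort("`n_rep` must be at least 10.")
  age_cols <- intersect(c("age", "age2"), colnames(X))

  one_rep <- function(r) {
    rep_seed <- seed + r
    with_seed(rep_seed, {
      idx <- seq_len(nrow(Y))
      if (!is.null(subsample_rule)) {
        idx <- age_bin_subsample(X[, "age"], subsample_rule$bin_width,
                                 subsample_rule$per_bin)
      }
      if (length(idx) < ncol(X) + 2) {
        abort("subsample too small for the design.")
      }
      Xs <- X[idx, , drop = FALSE]
      Ys <- Y[idx, , drop = FALSE]
      ms <- mdi[idx]
      perm <- sample.int(length(idx))
      Xs[, age_cols] <- Xs[perm, age_cols, drop = FALSE]
      w <- if (mode == "wls") {
        reml_estimate(Ys, Xs, build_basis(ms, powers))$w
      }
      fit <- fit_glm(Ys, Xs, w)
      map <- f_test(fit, age_cols)
      n_sig <- nrow(fwe_voxel(map, alpha))
      pos_cl <- NA
      if (cluster) {
        cl <- cluster_inference(Ys, Xs, age_cols, geometry, weights = w,
                                cft_p = cft_p, n_perm = n_perm_cluster,
                                seed = rep_seed)
        pos_cl <- nrow(cl) > 0 && any(cl$p_fwe <= alpha)
      }
      tibble(rep = r, seed = rep_seed, n_sig_voxel = n_sig,
             positive_voxel = n_sig > 0, positive_cluster = pos_cl)
    })
  }
  reps <- dplyr::bind_rows(purrr::map(seq_len(n_rep), one_rep))
  structure(
    list(n_replicates = n_rep,
         fpr_voxel = mean(reps$positive_voxel),
         fpr_cluster = if (cluster) mean(reps$positive_cluster) else NA_real_,
         alpha = alpha, mode = mode, replicates = reps),
    class = "specificity_result")
}

age_bin_subsample <- function(age, bin_width, per_bin) {
  bins <- floor(age / bin_width)
  idx <- unlist(lapply(split(seq_along(age), bins), function(i) {
    if (length(i) <= per_bin) i else sample(i, per_bin)
  }), use.names = FALSE)
  sort(idx)
}

#' Specificity analysis II: null two-sample comparisons
#'
#' Within a cohort with no true group structure, repeatedly assigns `N1`
#' randomly chosen subjects to group 1 and the rest to group 2, runs the
#' (weighted) two-sample t test with covariates, and records familywise
#' false positives. Unbalanced splits (`N1` small) are where group
#' comparisons are fragile.
#'
#' @param Y subjects x voxels matrix.
#' @param covariates matrix/data frame of nuisance covariates (no group).
#' @param mdi per-subject MDI values.
#' @param N1 size of the first group (2 <= N1 < N).
#' @param mode,n_rep,seed,powers,alpha,cluster,geometry,cft_p,n_perm_cluster
#'   as in [specificity_scramble()].
#' @return a `specificity_result`.
#' @export
specificity_two_sample <- function(Y, covariates, mdi, N1,
                                   mode = c("wls", "ols"),
                                   n_rep = 500L, seed = 1L, powers = 3,
                                   alpha = 0.05, cluster = FALSE,
                                   geometry = NULL, cft_p = 0.001,
                                   n_perm_cluster = 200L) {
  mode <- match.arg(mode)
  Y <- check_image_matrix(Y)
  n <- nrow(Y)
  if (N1 < 2 || N1 >= n) abort("`N1` must satisfy 2 <= N1 < N.")
  if (n_rep < 10) abort("`n_rep` must be at least 10.")
  cv <- if (!is.null(covariates)) as.matrix(as.data.frame(covariates))

  one_rep <- function(r) {
    rep_seed <- seed + r
    with_seed(rep_seed, {
      g <- rep(0L, n)
      g[sample.int(n, N1)] <- 1L
      Xg <- cbind(intercept = 1, group = g)
      if (!is.null(cv)) Xg <- cbind(Xg, cv)
      w <- if (mode == "wls") {
        reml_estimate(Y, Xg, build_basis(mdi, powers))$w
      }
      map <- two_sample_t(Y, g, covariates = cv, weights = w,
                          geometry = geometry)
      n_sig <- nrow(fwe_voxel(map, alpha))
      pos_cl <- NA
      if (cluster) {
        cl <- cluster_inference(Y, Xg, "group", geometry, weights = w,
                                cft_p = cft_p, n_perm = n_perm_cluster,
                                seed = rep_seed)
        pos_cl <- nrow(cl) > 0 && any(cl$p_fwe <= alpha)
      }
      tibble(rep = r, seed = rep_seed, n_sig_voxel = n_sig,
             positive_voxel = n_sig > 0, positive_cluster = pos_cl)
    })
  }
  reps <- dplyr::bind_rows(purrr::map(seq_len(n_rep), one_rep))
  structure(
    list(n_replicates = n_rep, N1 = N1,
         fpr_voxel = mean(reps$positive_voxel),
         fpr_cluster = if (cluster) mean(reps$positive_cluster) else NA_real_,
         alpha = alpha, mode = mode, replicates = reps),
    class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("<specificity_result> %s, %d replicates\n", toupper(x$mode),
              x$n_replicates))
  cat(sprintf("  voxel-level FWE false-positive rate: %.4f (alpha %.2f)\n",
              x$fpr_voxel, x$alpha))
  if (!is.na(x$fpr_cluster)) {
    cat(sprintf("  cluster-level FWE false-positive rate: %.4f\n", x$fpr_cluster))
  }
  invisible(x)
}

#' Quality-control exclusion analysis
#'
#' The conventional alternative to weighting: for each fraction `f`, discard
#' the `ceiling(f * N)` images with the highest MDI (ties broken by subject
#' order), refit by OLS, and summarise residual heteroscedasticity and the
#' age-effect F map on the retained subjects.
#'
#' @param Y subjects x voxels matrix.
#' @param X design matrix.
#' @param mdi per-subject MDI values.
#' @param fractions exclusion fractions in `[0, 0.5]` (default the
#'   conventional ladder 0, 0.03, 0.07, 0.13, 0.20, 0.30).
#' @param contrast_columns columns for the F test (default the age columns).
#' @param alpha voxel FWE level for the significant-voxel count.
#' @param order polynomial order for the heteroscedasticity R-squared.
#' @return tibble, one row per fraction: `fraction`, `n_excluded`,
#'   `n_retained`, `hetero_r2`, `n_sig_voxels`, `max_f`, `sig_voxels`
#'   (list-column of significant voxel indices).
#' @export
exclusion_analysis <- function(Y, X, mdi, fractions = c(0, 0.03, 0.07, 0.13, 0.20, 0.30),
                               contrast_columns = NULL, alpha = 0.05,
                               order = 3) {
  Y <- check_image_matrix(Y)
  X <- check_design(X, nrow(Y))
  if (any(fractions < 0 | fractions > 0.5)) abort("`fractions` must lie in [0, 0.5].")
  contrast_columns <- contrast_columns %||% intersect(c("age", "age2"), colnames(X))
  n <- nrow(Y)
  ord <- order(mdi, seq_along(mdi))   # ascending MDI, stable tie-break
  rows <- purrr::map(fractions, function(f) {
    n_drop <- ceiling(f * n)
    keep <- sort(if (n_drop == 0) seq_len(n) else head(ord, n - n_drop))
    if (length(keep) <= ncol(X) + 2) {
      abort(sprintf("fraction %.2f retains too few subjects for the design.", f))
    }
    fit <- fit_glm(Y[keep, , drop = FALSE], X[keep, , drop = FALSE])
    hr <- hetero_r2(residual_spatial_variance(fit)$var_eps, mdi[keep], order)
    map <- f_test(fit, contrast_columns)
    sig <- fwe_voxel(map, alpha)
    tibble(fraction = f, n_excluded = n_drop, n_retained = length(keep),
           hetero_r2 = hr$r2, n_sig_voxels = nrow(sig),
           max_f = max(map$statistic), sig_voxels = list(sig$voxel))
  })
  dplyr::bind_rows(rows)
}

#' MDI-as-covariate comparison
#'
#' The design-matrix alternative to weighting: augments the design with the
#' mean-centred first to fourth powers of the MDI, F-tests those columns,
#' and runs the heteroscedasticity diagnostics on the augmented model's
#' residuals. Mean-shift regressors cannot absorb a *variance* effect, so
#' under OLS the residuals stay heteroscedastic.
#'
#' @param Y subjects x voxels matrix.
#' @param X design matrix.
#' @param mdi per-subject MDI values.
#' @param mode "ols" or "wls" (REML weights with basis `powers`).
#' @param powers MDI powers for the REML basis in WLS mode.
#' @param max_power highest MDI power inserted as a covariate (default 4).
#' @param alpha voxel FWE level.
#' @param ... passed to [diagnose()].
#' @return list with `statmap` (F test of the MDI columns), `diagnostics`,
#'   `frac_sig_voxels` (FWE-significant fraction), and `condition_number`
#'   of the augmented design.
#' @export
covariate_comparison <- function(Y, X, mdi, mode = c("ols", "wls"),
                                 powers = 3, max_power = 4, alpha = 0.05, ...) {
  mode <- match.arg(mode)
  Y <- check_image_matrix(Y)
  X <- check_design(X, nrow(Y))
  if (nrow(Y) <= ncol(X) + max_power + 2) {
    abort("too few subjects for the augmented design.")
  }
  M <- vapply(seq_len(max_power), function(a) {
    m <- mdi^a
    m - mean(m)
  }, numeric(nrow(Y)))
  colnames(M) <- paste0("mdi", seq_len(max_power))
  Xa <- cbind(X, M)
  kappa_a <- kappa(Xa, exact = TRUE)
  if (qr(Xa)$rank < ncol(Xa)) {
    abort(sprintf(
      "augmented design is rank deficient (condition number %.3g); MDI powers are collinear.",
      kappa_a))
  }
  w <- if (mode == "wls") reml_estimate(Y, Xa, build_basis(mdi, powers))$w
  fit <- fit_glm(Y, Xa, w)
  map <- f_test(fit, colnames(M))
  diag <- diagnose(fit, mdi, ...)
  list(statmap = map, diagnostics = diag,
       frac_sig_voxels = nrow(fwe_voxel(map, alpha)) / nrow(map),
       condition_number = kappa_a)
}

#' Regional noise-model selection
#'
#' Reruns ELBO-based model selection separately within each region of an
#' integer label image, to map where the global noise model is locally
#' optimal.
#'
#' @param Y subjects x voxels matrix.
#' @param X design matrix.
#' @param mdi per-subject MDI values.
#' @param labels integer region label per voxel column (0 = background), or a
#'   3D label array matching `geometry`.
#' @param candidate_bases list of power vectors, as in [select_noise_model()].
#' @param geometry required when `labels` is a 3D array.
#' @param min_voxels regions smaller than this are skipped with a warning.
#' @param ... passed to [reml_estimate()].
#' @return tibble: `region`, `n_voxels`, `best_powers`, `elbo_gain` (best
#'   model vs basis {0}), `skipped`.
#' @export
regional_elbo <- function(Y, X, mdi, labels, candidate_bases,
                          geometry = NULL, min_voxels = 50L, ...) {
  Y <- check_image_matrix(Y)
  if (is.array(labels) && length(dim(labels)) == 3) {
    if (is.null(geometry)) abort("`geometry` is required for a 3D label image.")
    labels <- as.integer(labels[geometry$coords])
  }
  labels <- as.integer(labels)
  if (length(labels) != ncol(Y)) abort("`labels` length must match the voxel count.")
  regions <- sort(unique(labels[labels > 0]))
  if (length(regions) == 0) abort("label image contains no regions.")
  rows <- purrr::map(regions, function(rg) {
    vox <- which(labels == rg)
    if (length(vox) < min_voxels) {
      warn(sprintf("region %d has %d voxels (< %d); skipped.", rg,
                   length(vox), min_voxels))
      return(tibble(region = rg, n_voxels = length(vox),
                    best_powers = NA_character_, elbo_gain = NA_real_,
                    skipped = TRUE))
    }
    sel <- select_noise_model(Y[, vox, drop = FALSE], X, mdi,
                              candidate_bases, ...)
    best <- sel[!sel$failed, ][1, ]
    tibble(region = rg, n_voxels = length(vox),
           best_powers = best$powers, elbo_gain = best$elbo_gain,
           skipped = FALSE)
  })
  dplyr::bind_rows(rows)
}
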