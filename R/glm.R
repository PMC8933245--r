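#' Fit a mass-univariate general linear model
#'
#' Fits `Y = X beta + eps` voxel-wise by ordinary least squares, or — when
#' per-image weights `W = V^(-1/2)` are supplied — by weighted least squares
#' as OLS on the whitened pair `(W Y, W X)`. One QR factorisation of the
#' (whitened) design serves all voxels.
#'
#' @param Y subjects x voxels data matrix (or a `quiqir_cohort`, whose `Y`
#'   and `X` are used).
#' @param X design matrix with named columns; ignored when `Y` is a cohort
#'   unless supplied explicitly.
#' @param weights optional per-subject weights: a positive vector, diagonal
#'   matrix, or a `quiqir_reml` fit.
#' @return a `quiqir_glm` object: `betas` (p x voxels), `residuals`
#'   (whitened when weighted), `fitted` (whitened scale), `sigma2` (per-voxel
#'   residual variance, RSS/dof), `dof` = N - rank(X), `weights` (or NULL),
#'   `X`, `Xw`, `Yw`, `qr`, `geometry`.
#' @export
fit_glm <- function(Y, X = NULL, weights = NULL) {
  geometry <- NULL
  if (inherits(Y, "quiqir_cohort")) {
    if (is.null(X)) X <- Y$X
    geometry <- Y$geometry
    Y <- Y$Y
  }
  Y <- check_image_matrix(Y)
  X <- check_design(X, nrow(Y))
  n <- nrow(Y)
  w <- if (!is.null(weights)) as_weight_vector(weights, n)
  Yw <- if (is.null(w)) Y else Y * w
  Xw <- if (is.null(w)) X else X * w
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) abort("design matrix is rank deficient after weighting.")
  betas <- qr.coef(qrX, Yw)
  res <- qr.resid(qrX, Yw)
  dof <- n - ncol(X)
  leverage <- rowSums(qr.Q(qrX)^2)
  structure(
    list(betas = betas, residuals = res, fitted = Yw - res,
         sigma2 = colSums(res^2) / dof, dof = dof, leverage = leverage,
         weights = w, X = X, Xw = Xw, Yw = Yw, qr = qrX,
         geometry = geometry),
    class = "quiqir_glm")
}

new_statmap <- function(stat, p, type, contrast, df1, df2, geometry = NULL) {
  out <- tibble(voxel = seq_along(stat), statistic = as.numeric(stat),
                p = as.numeric(p))
  structure(out, class = c("quiqir_statmap", class(out)),
            type = type, contrast = contrast, df1 = df1, df2 = df2,
            geometry = geometry)
}

#' Voxel-wise F test of a set of design columns
#'
#' Extra-sum-of-squares F comparing the full model against the model with the
#' contrast columns removed; p-values from `F(df1 = #columns, df2 = dof)`.
#'
#' @param fit a [fit_glm()] object.
#' @param contrast_columns column names (or indices) of the design to test
#'   jointly, e.g. `c("age", "age2")`.
#' @return a `quiqir_statmap` tibble: `voxel`, `statistic`, `p`, with the
#'   test metadata in attributes.
#' @export
f_test <- function(fit, contrast_columns) {
  stopifnot(inherits(fit, "quiqir_glm"))
  cols <- resolve_columns(fit$X, contrast_columns)
  if (length(cols) == 0) abort("empty contrast.")
  rss1 <- colSums(fit$residuals^2)
  X0 <- fit$Xw[, -cols, drop = FALSE]
  rss0 <- if (ncol(X0) == 0) colSums(fit$Yw^2) else colSums(qr.resid(qr(X0), fit$Yw)^2)
  df1 <- length(cols)
  fstat <- ((rss0 - rss1) / df1) / (rss1 / fit$dof)
  # guard against floating-point dust when a model fits (near-)exactly
  scale0 <- pmax(colSums(fit$Yw^2), .Machine$double.xmin)
  zero1 <- rss1 <= 1e-12 * scale0
  fstat[zero1] <- ifelse(rss0[zero1] - rss1[zero1] > 1e-12 * scale0[zero1], Inf, 0)
  fstat <- pmax(fstat, 0)
  new_statmap(fstat, pf(fstat, df1, fit$dof, lower.tail = FALSE),
              type = "F",
              contrast = paste(colnames(fit$X)[cols], collapse = "+"),
              df1 = df1, df2 = fit$dof, geometry = fit$geometry)
}

resolve_columns <- function(X, columns) {
  if (is.character(columns)) {
    missing <- setdiff(columns, colnames(X))
    if (length(missing)) {
      abort(sprintf("contrast column(s) not in design: %s",
                    paste(missing, collapse = ", ")))
    }
    match(columns, colnames(X))
  } else {
    columns <- as.integer(columns)
    if (any(columns < 1 | columns > ncol(X))) abort("contrast index out of range.")
    columns
  }
}

#' Voxel-wise two-sample t test with covariates
#'
#' Tests the group-difference coefficient in a (weighted) GLM containing an
#' intercept, the group indicator, and any covariates.
#'
#' @param Y subjects x voxels matrix.
#' @param group_labels vector with exactly two levels.
#' @param covariates optional matrix/data frame of nuisance covariates.
#' @param weights optional weights, as in [fit_glm()].
#' @param geometry optional voxel geometry for downstream cluster inference.
#' @return a `quiqir_statmap` tibble (`statistic` = t of group 2 minus group
#'   1; two-sided `p`).
#' @export
two_sample_t <- function(Y, group_labels, covariates = NULL, weights = NULL,
                         geometry = NULL) {
  Y <- check_image_matrix(Y)
  g <- as.factor(group_labels)
  if (nlevels(g) != 2) abort("`group_labels` must have exactly two levels.")
  if (any(table(g) == 0)) abort("both groups must be non-empty.")
  X <- cbind(intercept = 1, group = as.numeric(g == levels(g)[2]))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    colnames(cv) <- colnames(cv) %||% paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  fit <- fit_glm(Y, X, weights)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(fit$sigma2 * XtXinv[2, 2])
  tstat <- fit$betas["group", ] / se
  # exactly-fitting voxels leave only floating-point dust in the residuals
  zero_var <- fit$sigma2 <= 1e-20 * pmax(colMeans(fit$Yw^2), .Machine$double.xmin)
  tstat[se == 0 | zero_var] <- 0
  new_statmap(tstat, 2 * pt(abs(tstat), fit$dof, lower.tail = FALSE),
              type = "t", contrast = "group", df1 = 1, df2 = fit$dof,
              geometry = geometry)
}

#' Voxel-level familywise-error control (Bonferroni)
#'
#' A voxel is significant iff `p <= alpha / N_voxels`. Bonferroni is
#' conservative and assumption-free, in place of random-field-theory
#' correction.
#'
#' @param map a `quiqir_statmap`.
#' @param alpha familywise alpha in (0, 1).
#' @return the significant rows of `map` (possibly zero rows), with the
#'   per-voxel threshold in attribute `threshold`.
#' @export
fwe_voxel <- function(map, alpha = 0.05) {
  stopifnot(inherits(map, "quiqir_statmap"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  thr <- alpha / nrow(map)
  out <- map[map$p <= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Cluster-level inference by permutation
#'
#' Thresholds the voxel-wise map at an uncorrected cluster-forming p-value,
#' labels supra-threshold voxels into connected components on the voxel grid
#' (26- or 6-neighbourhood), and assigns each cluster a familywise-error
#' p-value from the permutation null distribution of the maximum cluster
#' extent. Permutation follows Freedman-Lane: the reduced model (without the
#' contrast columns) is fitted once, its residuals are permuted, and the full
#' test statistic is recomputed on `fitted_reduced + permuted residuals`.
#'
#' @param Y subjects x voxels matrix.
#' @param X design matrix.
#' @param contrast_columns columns to test (as in [f_test()]).
#' @param geometry list with `dim` (3D grid) and `coords` (voxels x 3), as in
#'   cohort objects.
#' @param weights optional weights, as in [fit_glm()].
#' @param cft_p cluster-forming threshold (uncorrected p), default 0.001.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param connectivity 26 (default) or 6.
#' @param alpha reported significance cutoff (annotation only).
#' @return tibble of clusters: `cluster`, `n_voxels`, `peak_voxel`,
#'   `peak_stat`, `peak_x/y/z`, `p_fwe`; zero rows when nothing survives the
#'   forming threshold.
#' @export
cluster_inference <- function(Y, X, contrast_columns, geometry,
                              weights = NULL, cft_p = 0.001,
                              n_perm = 500L, seed = 1L,
                              connectivity = 26, alpha = 0.05) {
  if (is.null(geometry)) abort("voxel geometry is required for cluster inference.")
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  fit <- fit_glm(Y, X, weights)
  obs <- f_test(fit, contrast_columns)
  thr_stat <- qf(cft_p, attr(obs, "df1"), attr(obs, "df2"), lower.tail = FALSE)
  lab <- label_clusters(obs$statistic > thr_stat, geometry, connectivity)
  empty <- tibble(cluster = integer(), n_voxels = integer(),
                  peak_voxel = integer(), peak_stat = numeric(),
                  peak_x = integer(), peak_y = integer(), peak_z = integer(),
                  p_fwe = numeric())
  if (max(lab) == 0) return(empty)

  cols <- resolve_columns(X, contrast_columns)
  X0w <- fit$Xw[, -cols, drop = FALSE]
  qr0 <- qr(X0w)
  fit0_hat <- fit$Yw - qr.resid(qr0, fit$Yw)
  res0 <- qr.resid(qr0, fit$Yw)
  n <- nrow(Y)
  qrF <- qr(fit$Xw)
  df1 <- attr(obs, "df1"); df2 <- attr(obs, "df2")

  max_null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    Yb <- fit0_hat + res0[sample.int(n), , drop = FALSE]
    rss1 <- colSums(qr.resid(qrF, Yb)^2)
    rss0 <- colSums(qr.resid(qr0, Yb)^2)
    fb <- ((rss0 - rss1) / df1) / (rss1 / df2)
    lb <- label_clusters(fb > thr_stat, geometry, connectivity)
    if (max(lb) == 0) 0L else max(tabulate(lb))
  }, integer(1)))

  ids <- seq_len(max(lab))
  sizes <- tabulate(lab, nbins = max(lab))
  rows <- purrr::map(ids, function(i) {
    vox <- which(lab == i)
    pk <- vox[which.max(obs$statistic[vox])]
    tibble(cluster = i, n_voxels = sizes[i], peak_voxel = pk,
           peak_stat = obs$statistic[pk],
           peak_x = geometry$coords[pk, 1], peak_y = geometry$coords[pk, 2],
           peak_z = geometry$coords[pk, 3],
           p_fwe = (1 + sum(max_null >= sizes[i])) / (n_perm + 1))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p_fwe, dplyr::desc(.data$n_voxels))
  attr(out, "alpha") <- alpha
  attr(out, "cft_stat") <- thr_stat
  out
}

# Label supra-threshold voxels into connected components.
# `supra` is a logical vector over the voxel columns; geometry maps columns
# to 3D grid coordinates. Returns integer labels (0 = sub-threshold).
label_clusters <- function(supra, geometry, connectivity = 26) {
  if (!connectivity %in% c(6, 26)) abort("`connectivity` must be 6 or 26.")
  lab <- integer(length(supra))
  vox <- which(supra)
  if (length(vox) == 0) return(lab)
  d <- geometry$dim
  arr <- array(0L, d)
  arr[geometry$coords[vox, , drop = FALSE]] <- seq_along(vox)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  # keep one of each +/- pair
  keep <- offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)
  offs <- offs[keep, , drop = FALSE]

  co <- geometry$coords[vox, , drop = FALSE]
  edges <- purrr::map(seq_len(nrow(offs)), function(r) {
    nb <- sweep(co, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) return(NULL)
    tgt <- arr[nb[ok, , drop = FALSE]]
    src <- which(ok)[tgt > 0]
    if (!length(src)) return(NULL)
    cbind(src, tgt[tgt > 0])
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0) {
    lab[vox] <- seq_along(vox)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(vox) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[vox] <- as.integer(comp)
  lab
}

#' Write a statistic map as NIfTI
#'
#' @param map a `quiqir_statmap` with voxel geometry.
#' @param path output path; a companion `*_p` file holds the p-values.
#' @param what "statistic" or "p".
#' @return `path`, invisibly.
#' @export
write_statmap <- function(map, path, what = c("statistic", "p")) {
  what <- match.arg(what)
  geometry <- attr(map, "geometry")
  if (is.null(geometry)) abort("stat map has no voxel geometry; cannot export NIfTI.")
  arr <- array(NA_real_, geometry$dim)
  arr[geometry$coords] <- map[[what]]
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}

#' @export
print.quiqir_statmap <- function(x, ...) {
  cat(sprintf("<quiqir_statmap> %s test of %s, df = (%s, %s), %d voxels\n",
              attr(x, "type"), attr(x, "contrast"),
              attr(x, "df1"), attr(x, "df2"), nrow(x)))
  NextMethod()
}
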