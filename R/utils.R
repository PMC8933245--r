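# internal helpers shared across modules

# Validate an N x V numeric matrix of voxel data.
check_image_matrix <- function(Y) {
  if (!is.matrix(Y) || !is.numeric(Y)) {
    abort("`Y` must be a numeric matrix (subjects x voxels).")
  }
  if (anyNA(Y) || any(!is.finite(Y))) {
    abort("`Y` must not contain missing or non-finite values.")
  }
  Y
}

# Validate / coerce a design matrix; requires full column rank.
check_design <- function(X, n = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(n) && nrow(X) != n) {
    abort(sprintf("design has %d rows but data has %d subjects.", nrow(X), n))
  }
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient.")
  }
  X
}

# Positive diagonal weights as a plain vector, from a vector, a diagonal
# matrix, or a reml fit.
as_weight_vector <- function(w, n) {
  if (inherits(w, "quiqir_reml")) w <- w$w
  if (is.matrix(w)) {
    if (any(w[row(w) != col(w)] != 0)) abort("weight matrix must be diagonal.")
    w <- diag(w)
  }
  w <- as.numeric(w)
  if (length(w) != n) abort(sprintf("weights must have length %d.", n))
  if (any(!is.finite(w)) || any(w <= 0)) abort("weights must be finite and positive.")
  w
}

# log|A| for a symmetric positive-definite matrix via Cholesky;
# signals a design-deficiency error if the factorisation fails.
logdet_pd <- function(A, what = "X' V^-1 X") {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    abort(sprintf("%s is singular or not positive definite (design deficiency).", what))
  }
  2 * sum(log(diag(R)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
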