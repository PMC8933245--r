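#' Build MDI basis functions for REML
#'
#' The noise covariance is modelled as `V = sum_i lambda_i Q_i` with diagonal
#' basis matrices `Q_i = diag(mdi^alpha_i)`. Power 0 gives the identity
#' (the homoscedastic component). By default the MDI vector is rescaled to
#' unit mean before powering, which conditions the hyperparameter scales;
#' this only rescales the `lambda_i` by `mean(mdi)^alpha_i` and leaves the
#' fitted covariance, weights and model ranking unchanged. Estimates are
#' reported back on the original MDI scale.
#'
#' @param mdi per-subject MDI values (s^-1), length >= 2, finite.
#' @param powers distinct real exponents alpha.
#' @param rescale rescale the MDI to unit mean before powering.
#' @return a `basis_set`: list with `powers`, `mdi` (original), `mdi_scaled`,
#'   `scale` (the mean divided out), and `Q` (n_subjects x n_powers matrix of
#'   diagonal entries on the scaled MDI).
#' @examples
#' build_basis(c(1, 2, 3), powers = 3, rescale = FALSE)$Q
#' @export
build_basis <- function(mdi, powers, rescale = TRUE) {
  mdi <- as.numeric(mdi)
  powers <- as.numeric(powers)
  if (length(mdi) < 2 || any(!is.finite(mdi))) {
    abort("`mdi` must be a finite vector of length >= 2.")
  }
  if (length(powers) == 0) abort("`powers` must be non-empty.")
  if (anyDuplicated(powers)) abort("`powers` must be distinct.")
  if (any(powers < 0) && any(mdi <= 0)) {
    abort("negative powers require strictly positive MDI values.")
  }
  if (any(powers != 0) && any(mdi < 0)) {
    abort("non-zero powers require non-negative MDI values.")
  }
  scale <- if (rescale) mean(mdi) else 1
  if (rescale && scale <= 0) abort("MDI mean must be positive to rescale.")
  mdi_scaled <- mdi / scale
  Q <- outer(mdi_scaled, powers, `^`)
  colnames(Q) <- paste0("mdi^", powers)
  structure(list(powers = powers, mdi = mdi, mdi_scaled = mdi_scaled,
                 scale = scale, Q = Q),
            class = "basis_set")
}

#' Restricted log-likelihood (ELBO) of a variance model
#'
#' Evaluates, up to a constant, the REML objective for hyperparameters
#' `lambda` given pooled voxel data: with `V = sum_i lambda_i Q_i` (diagonal)
#' and N the number of voxels,
#' `E = -(N/2) ln|V| - (N/2) ln|X' V^-1 X| - (1/2) sum_n r_n' V^-1 r_n`,
#' where `r_n` are the generalised-least-squares residuals of voxel n. The
#' middle term is the standard restricted-likelihood form with the inverse of
#' V inside; `form = "printed"` evaluates `ln|X' V X|` instead (kept for
#' audit).
#'
#' @param lambdas hyperparameter vector, one per basis power (on the scale of
#'   `basis$Q`, i.e. the rescaled MDI if the basis was built with
#'   `rescale = TRUE`).
#' @param Y subjects x voxels data matrix.
#' @param X design matrix.
#' @param basis a [build_basis()] object.
#' @param form `"inverse"` (standard) or `"printed"`.
#' @return scalar ELBO value.
#' @export
elbo <- function(lambdas, Y, X, basis, form = c("inverse", "printed")) {
  form <- match.arg(form)
  Y <- check_image_matrix(Y)
  X <- check_design(X, nrow(Y))
  S <- tcrossprod(Y) / ncol(Y)
  elbo_from_S(lambdas, S, X, basis$Q, ncol(Y), form)$elbo
}

# Core ELBO from the pooled second-moment matrix S = Y Y' / N_voxels.
# Returns the ELBO plus the pieces the scoring update reuses.
elbo_from_S <- function(lambdas, S, X, Q, n_vox, form = "inverse") {
  v <- drop(Q %*% lambdas)
  if (any(!is.finite(v)) || any(v <= 0)) return(list(elbo = -Inf))
  D <- 1 / v
  B <- X * D                                  # V^-1 X
  A <- crossprod(X, B)                        # X' V^-1 X
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    abort("X' V^-1 X is singular (design deficiency).")
  }
  ld_mid <- if (form == "inverse") {
    2 * sum(log(diag(R)))
  } else {
    logdet_pd(crossprod(X, X * v), "X' V X")
  }
  # REML projector P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1
  P <- -B %*% chol2inv(R) %*% t(B)
  diag(P) <- diag(P) + D
  trPS <- sum(P * S)
  e <- -(n_vox / 2) * (sum(log(v)) + ld_mid + trPS)
  list(elbo = e, v = v, P = P, trPS = trPS)
}

#' Estimate noise hyperparameters by REML
#'
#' Fisher-scoring ascent on the restricted log-likelihood of the pooled voxel
#' data: the diagonal noise covariance `V = sum_i lambda_i Q_i` is shared
#' across all voxels in the pool, with the pooled second-moment matrix
#' `S = Y Y' / N_voxels` as the sufficient statistic. With
#' `positivity = TRUE` (default) the ascent runs on log-scale multipliers so
#' every `lambda_i > 0`; otherwise lambdas are unconstrained (the covariance
#' must still be positive definite, which step-halving enforces). Accepted
#' iterations never decrease the ELBO (steps are halved on a decrease).
#'
#' @param Y subjects x voxels data matrix.
#' @param X design matrix (full column rank).
#' @param basis a [build_basis()] object.
#' @param positivity constrain all hyperparameters to be positive.
#' @param tol convergence tolerance on the relative ELBO change.
#' @param max_iter maximum scoring iterations.
#' @param form ELBO form, see [elbo()].
#' @return a `quiqir_reml` object: `lambdas` (on the original MDI scale),
#'   `lambdas_scaled` (on the unit-mean MDI scale the optimiser used),
#'   `powers`, `v` (per-subject variances, diag of V), `w` (= v^-1/2, the WLS
#'   weights), `elbo`, `trace` (accepted ELBO values), `converged`,
#'   `iterations`, `positivity`, `basis`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 60, n_voxels = 300, seed = 2))
#' fit <- reml_estimate(co$Y, co$X, build_basis(co$mdi, 0))
#' fit$lambdas  # close to 1, the generating variance
#' @export
reml_estimate <- function(Y, X, basis, positivity = TRUE,
                          tol = 1e-8, max_iter = 128L,
                          form = c("inverse", "printed")) {
  form <- match.arg(form)
  Y <- check_image_matrix(Y)
  X <- check_design(X, nrow(Y))
  stopifnot(inherits(basis, "basis_set"))
  n <- nrow(Y); n_vox <- ncol(Y); k <- ncol(basis$Q)
  if (n <= ncol(X) + k) {
    abort("need more subjects than design rank + number of basis functions.")
  }

  S <- tcrossprod(Y) / n_vox
  Q <- basis$Q

  # initial lambdas: pooled OLS residual variance split equally across
  # components (each scaled by its mean basis diagonal)
  qrX <- qr(X)
  res0 <- qr.resid(qrX, Y)
  s2 <- sum(res0^2) / (n_vox * (n - ncol(X)))
  lam <- s2 / (k * colMeans(Q))
  if (any(!is.finite(lam)) || any(lam <= 0)) lam <- rep(s2 / k, k)

  st <- elbo_from_S(lam, S, X, Q, n_vox, form)
  if (!is.finite(st$elbo)) abort("initial variance model is not positive definite.")
  trace <- st$elbo
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    P <- st$P
    M <- P %*% S %*% P
    g <- (n_vox / 2) * drop(crossprod(Q, diag(M) - diag(P)))
    H <- (n_vox / 2) * crossprod(Q, (P * P) %*% Q)
    if (positivity) {
      # scoring on theta = log(lambda)
      g_t <- g * lam
      H_t <- H * tcrossprod(lam)
      diag(H_t) <- diag(H_t) + 1e-8 * max(diag(H_t), 1e-300)
      dth <- tryCatch(solve(H_t, g_t), error = function(e) g_t / diag(H_t))
      dth <- pmin(pmax(dth, -8), 8)           # cap log-steps
      step <- 1
      repeat {
        lam_new <- lam * exp(step * dth)
        st_new <- elbo_from_S(lam_new, S, X, Q, n_vox, form)
        if (is.finite(st_new$elbo) && st_new$elbo >= st$elbo - 1e-10) break
        step <- step / 2
        if (step < 1e-12) { st_new <- st; lam_new <- lam; break }
      }
    } else {
      diag(H) <- diag(H) + 1e-10 * max(diag(H), 1e-300)
      dl <- tryCatch(solve(H, g), error = function(e) g / diag(H))
      step <- 1
      repeat {
        lam_new <- lam + step * dl
        st_new <- elbo_from_S(lam_new, S, X, Q, n_vox, form)
        if (is.finite(st_new$elbo) && st_new$elbo >= st$elbo - 1e-10) break
        step <- step / 2
        if (step < 1e-12) { st_new <- st; lam_new <- lam; break }
      }
    }
    dE <- st_new$elbo - st$elbo
    lam <- lam_new
    st <- st_new
    trace <- c(trace, st$elbo)
    if (abs(dE) < tol * max(1, abs(st$elbo))) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("REML did not converge in %d iterations (last ELBO change %.3g).",
                 max_iter, trace[length(trace)] - trace[length(trace) - 1]))
  }

  v <- st$v
  structure(
    list(lambdas = setNames(lam / basis$scale^basis$powers,
                            paste0("mdi^", basis$powers)),
         lambdas_scaled = setNames(lam, paste0("mdi^", basis$powers)),
         powers = basis$powers, v = v, w = 1 / sqrt(v),
         elbo = st$elbo, trace = trace, converged = converged,
         iterations = iter, positivity = positivity, form = form,
         n_subjects = n, n_voxels = n_vox, basis = basis),
    class = "quiqir_reml")
}

#' Per-image whitening weights from a noise estimate
#'
#' `W = V^(-1/2)`: the diagonal weights that whiten the data for the weighted
#' least-squares analysis, so `W V W' = I`.
#'
#' @param estimate a `quiqir_reml` fit, or a positive vector of V's diagonal.
#' @return numeric vector of weights `w_j = v_j^(-1/2)`.
#' @export
compute_weights <- function(estimate) {
  v <- if (inherits(estimate, "quiqir_reml")) estimate$v else as.numeric(estimate)
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("all diagonal entries of V must be positive.")
  }
  1 / sqrt(v)
}

#' Select the best MDI noise model by ELBO
#'
#' Runs [reml_estimate()] for each candidate set of MDI powers and ranks the
#' candidates by ELBO (descending). The gain over the homoscedastic model
#' (basis `{0}`, i.e. the OLS assumption) is reported per candidate. The
#' restricted likelihood itself penalises complexity, so adding powers beyond
#' the generating one yields no material gain.
#'
#' @param Y subjects x voxels data matrix.
#' @param X design matrix.
#' @param mdi per-subject MDI values.
#' @param candidate_bases list of power vectors, e.g. `list(1, 2, 3, c(1, 2, 3, 4))`.
#' @param ... passed to [reml_estimate()].
#' @return a tibble, one row per candidate, ranked by ELBO: `powers` (label),
#'   `elbo`, `elbo_gain` (vs basis {0}), `lambdas` (list-column, original MDI
#'   scale), `converged`, `failed`, `rank`. Failed candidates rank last.
#' @export
select_noise_model <- function(Y, X, mdi, candidate_bases, ...) {
  if (length(candidate_bases) < 2) abort("need at least 2 candidate bases.")
  fit0 <- reml_estimate(Y, X, build_basis(mdi, 0), ...)
  rows <- purrr::map(candidate_bases, function(p) {
    fit <- tryCatch(reml_estimate(Y, X, build_basis(mdi, p), ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("candidate {%s} failed: %s", paste(p, collapse = ","),
                   conditionMessage(fit)))
      tibble(powers = paste(p, collapse = ","), elbo = NA_real_,
             elbo_gain = NA_real_, lambdas = list(NULL),
             converged = NA, failed = TRUE)
    } else {
      tibble(powers = paste(p, collapse = ","), elbo = fit$elbo,
             elbo_gain = fit$elbo - fit0$elbo, lambdas = list(fit$lambdas),
             converged = fit$converged, failed = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$failed, dplyr::desc(.data$elbo))
  out$rank <- seq_len(nrow(out))
  out
}

#' @export
print.quiqir_reml <- function(x, ...) {
  cat(sprintf("<quiqir_reml> %d subjects, %d voxels pooled\n",
              x$n_subjects, x$n_voxels))
  cat(sprintf("  powers {%s}, positivity %s, %s in %d iterations\n",
              paste(x$powers, collapse = ", "),
              if (x$positivity) "on" else "off",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  lambda (original MDI scale):\n")
  print(signif(x$lambdas, 4))
  cat(sprintf("  ELBO %.4f\n", x$elbo))
  invisible(x)
}
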