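# Independent reference implementations used to check the fast paths.
# These are deliberately naive: dense matrices, per-voxel loops, stats::lm.

# Dense generalised least squares, voxel by voxel.
oracle_gls <- function(Y, X, V) {
  Vi <- solve(V)
  A <- solve(t(X) %*% Vi %*% X)
  sapply(seq_len(ncol(Y)), function(n) drop(A %*% t(X) %*% Vi %*% Y[, n]))
}

# Term-by-term evaluation of the restricted log-likelihood:
# E = -(N/2) ln|V| - (N/2) ln|X' V^-1 X| - (1/2) sum_n r_n' V^-1 r_n
# with r_n the GLS residual of voxel n. `Q` holds the basis diagonals.
oracle_elbo <- function(lambdas, Y, X, Q) {
  v <- drop(Q %*% lambdas)
  if (any(v <= 0)) return(-Inf)
  V <- diag(v)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  quad <- 0
  for (n in seq_len(ncol(Y))) {
    beta <- solve(A, t(X) %*% Vi %*% Y[, n])
    r <- Y[, n] - X %*% beta
    quad <- quad + drop(t(r) %*% Vi %*% r)
  }
  nv <- ncol(Y)
  -(nv / 2) * determinant(V, logarithm = TRUE)$modulus[1] -
    (nv / 2) * determinant(A, logarithm = TRUE)$modulus[1] -
    quad / 2
}

# Maximise the naive restricted likelihood over log-lambda (the
# "grid-search refined" oracle optimum), started at the generating values.
oracle_elbo_opt <- function(start_lambdas, Y, X, Q) {
  obj <- function(th) -oracle_elbo(exp(th), Y, X, Q)
  opt <- optim(log(start_lambdas), obj, method = "L-BFGS-B",
               control = list(factr = 10, pgtol = 0, maxit = 500))
  list(lambdas = exp(opt$par), elbo = -opt$value)
}

# Per-voxel two-parameter regression of log signal on echo time via the
# normal equations.
oracle_loglinear_r2star <- function(signals, te) {
  apply(signals, 1, function(s) {
    Z <- cbind(1, te)
    ab <- solve(t(Z) %*% Z, t(Z) %*% log(s))
    -ab[2] * 1000
  })
}

# Engle LM statistic by explicit auxiliary lm().
oracle_arch_lm <- function(r, max_lag) {
  u <- r^2
  n <- length(u)
  d <- as.data.frame(stats::embed(u, max_lag + 1))
  names(d) <- c("y", paste0("l", seq_len(max_lag)))
  fit <- lm(y ~ ., data = d)
  (n - max_lag) * summary(fit)$r.squared
}

# Two-pass spatial variance.
oracle_variance <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

# A small heteroscedastic cohort used across tests.
make_cubic_cohort <- function(n_subjects = 150, n_voxels = 1000, seed = 1,
                              lambdas = 0.05, powers = 3, ...) {
  generate_cohort(cohort_spec(n_subjects = n_subjects, n_voxels = n_voxels,
                              noise = list(lambdas = lambdas, powers = powers),
                              seed = seed, ...))
}
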