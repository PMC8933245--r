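test_that("basis diagonals are elementwise powers of the MDI", {
  b <- build_basis(c(1, 2, 3), powers = 3, rescale = FALSE)
  expect_equal(unname(b$Q[, 1]), c(1, 8, 27))
  b0 <- build_basis(c(0.4, 2.2, 9), powers = 0)
  expect_equal(unname(b0$Q[, 1]), rep(1, 3))

  set.seed(2)
  mdi <- runif(25, 0.5, 6)
  b4 <- build_basis(mdi, powers = 1:4, rescale = FALSE)
  expect_equal(dim(b4$Q), c(25L, 4L))
  for (i in 1:4) expect_equal(unname(b4$Q[, i]), mdi^i)

  expect_error(build_basis(c(0, 1, 2), powers = -1), "negative powers")
  expect_error(build_basis(c(1, 2), powers = c(1, 1)), "distinct")
  expect_error(build_basis(c(1, 2), powers = numeric(0)), "non-empty")
})

test_that("REML with the identity basis reproduces the classical variance estimate", {
  co <- generate_cohort(cohort_spec(n_subjects = 60, n_voxels = 500, seed = 21))
  X <- co$X[, c("intercept", "age", "sex", "volume")]
  fit <- reml_estimate(co$Y, X, build_basis(co$mdi, 0))
  s2 <- sum(qr.resid(qr(X), co$Y)^2) / (500 * (60 - 4))
  expect_lt(abs(fit$lambdas[[1]] - s2) / s2, 1e-6)
  expect_true(fit$converged)
})

test_that("the ELBO agrees with a dense term-by-term oracle", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 20, n_voxels = 50,
    noise = list(lambdas = c(1, 0.05), powers = c(0, 3)), seed = 31))
  b <- build_basis(co$mdi, c(0, 3), rescale = FALSE)
  for (lam in list(c(1, 0.05), c(0.5, 0.2), c(2, 0.01))) {
    e1 <- elbo(lam, co$Y, co$X, b)
    e2 <- oracle_elbo(lam, co$Y, co$X, b$Q)
    expect_lt(abs(e1 - e2) / abs(e2), 1e-8)
  }
})

test_that("a duplicate basis function at lambda zero leaves the ELBO unchanged", {
  co <- generate_cohort(cohort_spec(n_subjects = 25, n_voxels = 40, seed = 5))
  b1 <- build_basis(co$mdi, c(0, 3), rescale = FALSE)
  # same variance model, padded with an extra cubic component at zero weight
  Q_dup <- cbind(b1$Q, b1$Q[, 2])
  b2 <- b1
  b2$Q <- Q_dup
  b2$powers <- c(0, 3, 3)
  e1 <- elbo(c(1.3, 0.07), co$Y, co$X, b1)
  e2 <- quiqir:::elbo_from_S(c(1.3, 0.07, 0),
                             tcrossprod(co$Y) / ncol(co$Y),
                             co$X, Q_dup, ncol(co$Y))$elbo
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("the fitted lambdas sit at a restricted-likelihood maximum", {
  co <- make_cubic_cohort(n_subjects = 120, n_voxels = 600, seed = 8,
                          lambdas = c(1, 0.05), powers = c(0, 3))
  b <- build_basis(co$mdi, c(0, 3))
  fit <- reml_estimate(co$Y, co$X, b)
  lam <- fit$lambdas_scaled
  e_hat <- elbo(lam, co$Y, co$X, b)
  expect_equal(e_hat, fit$elbo, tolerance = 1e-10)
  for (f in c(0.5, 2)) {
    expect_gte(e_hat, elbo(f * lam, co$Y, co$X, b))
  }
  # ELBO trace of accepted iterations never decreases
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("positivity drives an unsupported component to the boundary", {
  co <- generate_cohort(cohort_spec(n_subjects = 150, n_voxels = 1500, seed = 13))
  fit <- reml_estimate(co$Y, co$X, build_basis(co$mdi, c(0, 3)),
                       positivity = TRUE)
  # no MDI-related noise in the data: cubic weight collapses, identity
  # weight carries the residual variance (generating value 1)
  expect_lt(fit$lambdas[["mdi^3"]] / fit$lambdas[["mdi^0"]], 0.05)
  expect_lt(abs(fit$lambdas[["mdi^0"]] - 1), 0.1)
})

test_that("weights satisfy W V W' = I and match hand values", {
  expect_equal(compute_weights(c(4, 9, 25)), c(1 / 2, 1 / 3, 1 / 5))
  expect_equal(compute_weights(rep(1, 7)), rep(1, 7))
  set.seed(9)
  v <- exp(rnorm(40))
  w <- compute_weights(v)
  expect_lt(max(abs(w * v * w - 1)), 1e-12)
  expect_error(compute_weights(c(1, 0, 2)), "positive")
})

test_that("rescaling the MDI rescales lambdas but not weights or inference", {
  co <- make_cubic_cohort(n_subjects = 100, n_voxels = 500, seed = 17,
                          lambdas = c(1, 0.05), powers = c(0, 3))
  f1 <- reml_estimate(co$Y, co$X, build_basis(co$mdi, c(0, 3)))
  cc <- 3.7
  f2 <- reml_estimate(co$Y, co$X, build_basis(cc * co$mdi, c(0, 3)))
  expect_equal(unname(f2$lambdas), unname(f1$lambdas) * cc^-c(0, 3),
               tolerance = 1e-4)
  expect_equal(f2$w, f1$w, tolerance = 1e-6)
  m1 <- f_test(fit_glm(co$Y, co$X, f1$w), c("age", "age2"))
  m2 <- f_test(fit_glm(co$Y, co$X, f2$w), c("age", "age2"))
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-6)
})

test_that("model selection ranks the homoscedastic basis first on homoscedastic data", {
  co <- generate_cohort(cohort_spec(n_subjects = 120, n_voxels = 800, seed = 23))
  sel <- select_noise_model(co$Y, co$X, co$mdi, list(0, 1, 2))
  expect_equal(sel$powers[1], "0")
  expect_true(all(sel$elbo_gain[sel$powers == "0"] >= -1e-6))
})

test_that("degenerate designs and insufficient cohorts are rejected", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, n_voxels = 50, seed = 3))
  Xbad <- cbind(co$X, dup = co$X[, "age"])
  expect_error(reml_estimate(co$Y, Xbad, build_basis(co$mdi, 0)),
               "rank deficient")
  # pick a tiny subcohort with both sexes so only the size check can fire
  idx <- c(which(co$design$sex == 0)[1:4], which(co$design$sex == 1)[1:3])
  expect_error(reml_estimate(co$Y[idx, ], co$X[idx, ],
                             build_basis(co$mdi[idx], c(0, 3))),
               "more subjects")
})
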