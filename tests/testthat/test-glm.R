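test_that("exact data are fitted exactly and identity weights equal OLS", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, n_voxels = 40, seed = 2))
  beta <- matrix(rnorm(ncol(co$X) * 40), ncol(co$X), 40)
  Yx <- co$X %*% beta
  fit <- fit_glm(Yx, co$X)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_equal(unname(fit$betas), unname(beta), tolerance = 1e-9)

  fit_w1 <- fit_glm(co$Y, co$X, weights = rep(1, 30))
  fit_o <- fit_glm(co$Y, co$X)
  expect_equal(fit_w1$betas, fit_o$betas, tolerance = 1e-12)
  expect_equal(fit_w1$sigma2, fit_o$sigma2, tolerance = 1e-12)

  # residuals orthogonal to the whitened design
  expect_lt(max(abs(crossprod(fit_o$Xw, fit_o$residuals))), 1e-8)
})

test_that("WLS with known V equals the dense GLS oracle", {
  set.seed(33)
  n <- 30; p <- 4; nv <- 25
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(X) <- c("intercept", "a", "b", "c")
  v <- exp(rnorm(n, 0, 0.8))
  Y <- matrix(rnorm(n * nv, sd = sqrt(v)), n, nv)
  fit <- fit_glm(Y, X, weights = 1 / sqrt(v))
  orc <- oracle_gls(Y, X, diag(v))
  expect_lt(max(abs(unname(fit$betas) - orc)), 1e-10)
})

test_that("F tests equal the nested-model brute force and the t-squared identity", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, n_voxels = 50, seed = 4))
  fit <- fit_glm(co$Y, co$X)
  map <- f_test(fit, c("age", "age2"))
  # brute force: refit both models per voxel
  for (n in seq_len(50)) {
    y <- co$Y[, n]
    rss1 <- sum(lm.fit(co$X, y)$residuals^2)
    rss0 <- sum(lm.fit(co$X[, !colnames(co$X) %in% c("age", "age2")], y)$residuals^2)
    f_ref <- ((rss0 - rss1) / 2) / (rss1 / fit$dof)
    expect_lt(abs(map$statistic[n] - f_ref), 1e-10 * max(1, f_ref))
  }
  # single-column contrast equals the squared t statistic
  m1 <- f_test(fit, "age")
  XtXinv <- chol2inv(qr.R(fit$qr))
  tstat <- fit$betas["age", ] / sqrt(fit$sigma2 * XtXinv[2, 2])
  expect_equal(m1$statistic, unname(tstat^2), tolerance = 1e-10)
  expect_error(f_test(fit, character(0)), "empty|not in design")
})

test_that("null F-test p-values are uniform", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, n_voxels = 5000, seed = 44))
  map <- f_test(fit_glm(co$Y, co$X), c("age", "age2"))
  expect_gt(suppressWarnings(ks.test(map$p, "punif"))$p.value, 0.01)
})

test_that("two-sample t matches the pooled-variance formula and is symmetric", {
  set.seed(55)
  n1 <- 12; n2 <- 18
  g <- rep(c(0, 1), c(n1, n2))
  Y <- matrix(rnorm((n1 + n2) * 30), n1 + n2, 30)
  Y[g == 1, ] <- Y[g == 1, ] + 0.8
  map <- two_sample_t(Y, g)
  tref <- apply(Y, 2, function(y) {
    m1 <- mean(y[g == 0]); m2 <- mean(y[g == 1])
    sp <- sqrt(((n1 - 1) * var(y[g == 0]) + (n2 - 1) * var(y[g == 1])) / (n1 + n2 - 2))
    (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  })
  expect_lt(max(abs(map$statistic - tref)), 1e-10)

  # swapping the group labels flips the sign exactly
  map_sw <- two_sample_t(Y, 1 - g)
  expect_equal(map_sw$statistic, -map$statistic, tolerance = 1e-12)

  # identical groups with zero noise
  Y0 <- matrix(1, n1 + n2, 1) %*% t(rnorm(30))
  expect_true(all(two_sample_t(Y0, g)$statistic == 0))
  expect_error(two_sample_t(Y, rep(0, n1 + n2)), "two levels")
})

test_that("voxel FWE is Bonferroni", {
  p <- c(0.001, runif(99, 0.01, 1))
  map <- quiqir:::new_statmap(qf(p, 2, 30, lower.tail = FALSE), p, "F", "x", 2, 30)
  expect_equal(nrow(fwe_voxel(map, 0.05)), 0L)       # 0.001 > 0.05/100
  one <- quiqir:::new_statmap(5, 0.04, "F", "x", 2, 30)
  expect_equal(nrow(fwe_voxel(one, 0.05)), 1L)
  expect_error(fwe_voxel(map, 1.2), "alpha")
})

test_that("voxel FWE false-positive rate is controlled on null data", {
  set.seed(66)
  n <- 30; nv <- 200; n_rep <- 400
  X <- cbind(intercept = 1, x = rnorm(n))
  hits <- vapply(seq_len(n_rep), function(r) {
    Y <- matrix(rnorm(n * nv), n, nv)
    nrow(fwe_voxel(f_test(fit_glm(Y, X), "x"), 0.05)) > 0
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(hits), 0.05 + 2 * se)
})

test_that("connected components respect the connectivity scheme", {
  geom <- list(dim = c(4L, 4L, 1L),
               coords = as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1L)))
  supra <- rep(FALSE, 16)
  # two diagonal voxels: (1,1) and (2,2) touch under 26- but not 6-connectivity
  supra[c(1, 6)] <- TRUE
  l26 <- quiqir:::label_clusters(supra, geom, 26)
  l6 <- quiqir:::label_clusters(supra, geom, 6)
  expect_equal(max(l26), 1L)
  expect_equal(max(l6), 2L)
  expect_equal(max(quiqir:::label_clusters(rep(FALSE, 16), geom)), 0L)
})

test_that("an overwhelming activation cluster gets the smallest attainable p", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, grid_dim = c(6, 6, 6),
                                    seed = 77,
                                    effects = list(active_frac = 0.3,
                                                   beta_age = 0.25,
                                                   layout = "block")))
  cl <- cluster_inference(co$Y, co$X, c("age", "age2"), co$geometry,
                          cft_p = 0.001, n_perm = 100, seed = 5)
  expect_gt(nrow(cl), 0)
  expect_equal(min(cl$p_fwe), 1 / 101, tolerance = 1e-12)
})

test_that("the cluster-forming threshold passes about its nominal voxel fraction", {
  set.seed(88)
  rates <- vapply(1:40, function(r) {
    co <- generate_cohort(cohort_spec(n_subjects = 35, n_voxels = 2000, seed = r))
    map <- f_test(fit_glm(co$Y, co$X), c("age", "age2"))
    mean(map$p < 0.001)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.001), 5e-4)
})

test_that("cluster-level FWE rate is controlled on null data", {
  set.seed(99)
  geom_dim <- c(5L, 5L, 5L)
  n_rep <- 150
  hits <- vapply(seq_len(n_rep), function(r) {
    co <- generate_cohort(cohort_spec(n_subjects = 16, grid_dim = geom_dim,
                                      seed = 1000 + r))
    cl <- cluster_inference(co$Y, co$X[, c("intercept", "age", "sex")],
                            "age", co$geometry, cft_p = 0.01,
                            n_perm = 100, seed = r)
    nrow(cl) > 0 && any(cl$p_fwe <= 0.05)
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(hits), 0.05 + 2 * se)
})

test_that("F maps are invariant to affine rescaling of the data", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, n_voxels = 60, seed = 12))
  m1 <- f_test(fit_glm(co$Y, co$X), c("age", "age2"))
  m2 <- f_test(fit_glm(3.2 * co$Y + 10, co$X), c("age", "age2"))
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-9)
})

test_that("true-V weighting beats OLS in beta mean squared error", {
  wins <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(
      n_subjects = 80, n_voxels = 300, seed = 400 + s,
      noise = list(lambdas = c(1, 0.05), powers = c(0, 3)),
      effects = list(active_frac = 0.2, beta_age = 0.03)))
    w <- 1 / sqrt(1 + 0.05 * co$mdi^3)
    b_ols <- fit_glm(co$Y, co$X)$betas["age", ]
    b_wls <- fit_glm(co$Y, co$X, w)$betas["age", ]
    truth <- co$truth$beta["age", ]
    mean((b_wls - truth)^2) < mean((b_ols - truth)^2)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
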