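test_that("scrambled-age analysis of noiseless null data never fires", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, n_voxels = 60, seed = 14))
  beta <- matrix(0, ncol(co$X), 60, dimnames = list(colnames(co$X), NULL))
  beta["intercept", ] <- rnorm(60, 20, 2)
  beta["sex", ] <- 0.5
  Yx <- co$X %*% beta                          # exact, no age effect, no noise
  sp <- specificity_scramble(Yx, co$X, co$mdi, mode = "ols", n_rep = 20, seed = 3)
  expect_equal(sp$fpr_voxel, 0)
})

test_that("the replicate stream is reproducible and extendable", {
  co <- make_cubic_cohort(n_subjects = 60, n_voxels = 100, seed = 15,
                          lambdas = c(1, 0.05), powers = c(0, 3))
  s1 <- specificity_scramble(co$Y, co$X, co$mdi, mode = "ols", n_rep = 15, seed = 4)
  s2 <- specificity_scramble(co$Y, co$X, co$mdi, mode = "ols", n_rep = 30, seed = 4)
  expect_identical(s1$replicates, s2$replicates[1:15, ])
})

test_that("the age-bin subsampling rule caps each bin", {
  set.seed(16)
  age <- runif(200, 20, 80)
  idx <- quiqir:::age_bin_subsample(age, 5, 10)
  expect_true(all(table(floor(age[idx] / 5)) <= 10))
  expect_true(all(idx %in% seq_along(age)))
})

test_that("balanced null two-sample comparisons keep their FWE rate", {
  co <- generate_cohort(cohort_spec(n_subjects = 60, n_voxels = 200, seed = 17,
                                    design = list(age_range = c(56, 58))))
  sp <- specificity_two_sample(co$Y, co$design[, c("age", "volume")], co$mdi,
                               N1 = 30, mode = "ols", n_rep = 150, seed = 5)
  se <- sqrt(0.05 * 0.95 / 150)
  expect_lte(sp$fpr_voxel, 0.05 + 2 * se)
})

test_that("unbalanced group comparisons inflate false positives on heteroscedastic data", {
  co <- make_cubic_cohort(n_subjects = 100, n_voxels = 200, seed = 18,
                          lambdas = c(1, 0.05), powers = c(0, 3),
                          design = list(age_range = c(56, 58)))
  f2 <- specificity_two_sample(co$Y, NULL, co$mdi, N1 = 2, mode = "ols",
                               n_rep = 120, seed = 6)
  f30 <- specificity_two_sample(co$Y, NULL, co$mdi, N1 = 50, mode = "ols",
                                n_rep = 120, seed = 6)
  expect_gte(f2$fpr_voxel + 0.05, f30$fpr_voxel)  # monotone within MC error
})

test_that("exclusion at fraction zero reproduces the baseline OLS analysis", {
  co <- make_cubic_cohort(n_subjects = 80, n_voxels = 300, seed = 19,
                          effects = list(active_frac = 0.1, beta_age = 0.05))
  ex <- exclusion_analysis(co$Y, co$X, co$mdi, fractions = c(0, 0.3))
  fit <- fit_glm(co$Y, co$X)
  base_r2 <- hetero_r2(residual_spatial_variance(fit)$var_eps, co$mdi)$r2
  expect_equal(ex$hetero_r2[1], base_r2, tolerance = 1e-12)
  expect_equal(ex$n_retained, c(80L, 56L))
  expect_equal(ex$n_excluded, c(0L, 24L))
})

test_that("excluding high-MDI images reduces heteroscedasticity monotonically", {
  co <- make_cubic_cohort(n_subjects = 150, n_voxels = 1500, seed = 20)
  ex <- exclusion_analysis(co$Y, co$X, co$mdi,
                           fractions = c(0, 0.07, 0.2, 0.3))
  expect_true(all(diff(ex$hetero_r2) < 0))
})

test_that("MDI ties at the exclusion cut are broken deterministically", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, n_voxels = 50, seed = 21))
  mdi_tied <- rep(1:10, 3)
  a <- exclusion_analysis(co$Y, co$X, mdi_tied, fractions = 0.3)
  b <- exclusion_analysis(co$Y, co$X, mdi_tied, fractions = 0.3)
  expect_identical(a, b)
})

test_that("MDI covariates do not absorb variance heteroscedasticity but weights do", {
  co <- make_cubic_cohort(n_subjects = 150, n_voxels = 1000, seed = 22)
  cc_ols <- covariate_comparison(co$Y, co$X, co$mdi, mode = "ols")
  expect_gte(cc_ols$diagnostics$r2_poly, 0.5)
  cc_wls <- covariate_comparison(co$Y, co$X, co$mdi, mode = "wls", powers = 3)
  expect_lte(cc_wls$diagnostics$r2_poly, 0.2)
  expect_lt(cc_wls$frac_sig_voxels, cc_ols$frac_sig_voxels + 0.05)
  expect_error(covariate_comparison(co$Y, co$X, rep(2, 150)), "rank deficient")
})

test_that("regional selection recovers planted region-specific noise models", {
  spA <- cohort_spec(n_subjects = 150, n_voxels = 600, seed = 23,
                     noise = list(lambdas = 0.05, powers = 3))
  spB <- cohort_spec(n_subjects = 150, n_voxels = 600, seed = 23,
                     noise = list(lambdas = 0.3, powers = 2))
  coA <- generate_cohort(spA)
  coB <- generate_cohort(spB)          # same seed: same subjects, MDI, design
  expect_identical(coA$mdi, coB$mdi)
  Y <- cbind(coA$Y, coB$Y)
  labels <- rep(c(1L, 2L), each = 600)
  tab <- regional_elbo(Y, coA$X, coA$mdi, labels, list(1, 2, 3))
  expect_equal(tab$best_powers, c("3", "2"))
  expect_true(all(tab$elbo_gain > 0))

  # homogeneous case: every region picks the shared model
  lab2 <- rep(c(1L, 2L), 300)
  tab2 <- regional_elbo(coA$Y, coA$X, coA$mdi, lab2, list(2, 3))
  expect_true(all(tab2$best_powers == "3"))
})

test_that("undersized regions are skipped with a warning", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, n_voxels = 120, seed = 24))
  labels <- c(rep(1L, 110), rep(2L, 10))
  expect_warning(tab <- regional_elbo(co$Y, co$X, co$mdi, labels,
                                      list(0, 3), min_voxels = 50),
                 "skipped")
  expect_true(tab$skipped[tab$region == 2])
  expect_false(tab$skipped[tab$region == 1])
})
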