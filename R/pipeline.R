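#' Validate a pipeline run configuration
#'
#' A config (list or YAML file) describes one end-to-end analysis. Input is
#' one of: `simulate` (arguments for [cohort_spec()]), `y_csv` + `design_csv`
#' + `mdi_csv` (tabular data), `images` (text file listing one map NIfTI per
#' subject) + `design_csv` + `mdi_csv`, or `echoes` (CSV manifest of raw
#' multi-echo 4D NIfTIs: columns subject_id, path) + `echo_times` +
#' `wm_mask`, from which R2* maps and MDI values are computed. Analysis
#' settings: `powers` (REML basis), `positivity`, `contrast` (design columns
#' to F-test), `alpha`, `cluster`, `cft_p`, `n_perm`, `order` (check
#' polynomial), `seed`, `out_dir`.
#'
#' @param config list or path to a YAML file.
#' @return the validated config list (class `quiqir_config`).
#' @export
quiqi_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML path.")
  defaults <- list(powers = 3, positivity = TRUE, contrast = c("age", "age2"),
                   alpha = 0.05, cluster = FALSE, cft_p = 0.001,
                   n_perm = 500L, order = 3, seed = 1L, mask = NULL,
                   out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  if (length(config$powers) == 0) abort("`powers` must be non-empty.")
  if (config$alpha <= 0 || config$alpha >= 1) abort("`alpha` must be in (0, 1).")
  has_sim <- !is.null(config$simulate)
  has_tab <- !is.null(config$y_csv)
  has_img <- !is.null(config$images)
  has_ech <- !is.null(config$echoes)
  if (sum(has_sim, has_tab, has_img, has_ech) != 1) {
    abort("config must specify exactly one input: simulate, y_csv, images, or echoes.")
  }
  needed <- c(
    if (has_tab) c(config$y_csv, config$design_csv, config$mdi_csv),
    if (has_img) c(config$images, config$design_csv, config$mdi_csv),
    if (has_ech) c(config$echoes, config$design_csv, config$wm_mask)
  )
  missing <- needed[!vapply(needed, function(f) !is.null(f) && file.exists(f),
                            logical(1))]
  if (length(missing)) {
    abort(sprintf("missing input file(s): %s",
                  paste(unlist(missing), collapse = ", ")))
  }
  structure(config, class = c("quiqir_config", "list"))
}

load_pipeline_data <- function(config) {
  if (!is.null(config$simulate)) {
    spec_args <- config$simulate
    spec_args$seed <- spec_args$seed %||% config$seed
    co <- generate_cohort(do.call(cohort_spec, spec_args))
    return(list(Y = co$Y, X = co$X, design = co$design, mdi = co$mdi,
                geometry = co$geometry))
  }
  design <- as_tibble(read.csv(config$design_csv))
  if (!is.null(config$echoes)) {
    man <- read.csv(config$echoes)
    wm <- read_mask(config$wm_mask)
    maps <- lapply(man$path, function(p) {
      fit_r2star(read_multi_echo(p, config$echo_times))
    })
    mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
    Y <- do.call(rbind, lapply(maps, function(m) m$values[mask]))
    mdi <- vapply(maps, function(m) compute_mdi(m, wm)$mdi, numeric(1))
    d <- dim(wm)
    coords <- which(mask, arr.ind = TRUE)
    colnames(coords) <- c("x", "y", "z")
    return(list(Y = Y, X = build_design(design), design = design, mdi = mdi,
                geometry = list(dim = d, coords = coords)))
  }
  mdi_tbl <- read.csv(config$mdi_csv)
  mdi <- mdi_tbl$mdi
  if (!is.null(config$images)) {
    paths <- readLines(config$images)
    paths <- paths[nzchar(trimws(paths))]
    vols <- lapply(paths, function(p) as.array(RNifti::readNifti(p)))
    d <- dim(vols[[1]])
    mask <- if (!is.null(config$mask)) read_mask(config$mask) else {
      Reduce(`&`, lapply(vols, function(v) is.finite(v)))
    }
    Y <- do.call(rbind, lapply(vols, function(v) v[mask]))
    coords <- which(mask, arr.ind = TRUE)
    colnames(coords) <- c("x", "y", "z")
    geometry <- list(dim = d, coords = coords)
  } else {
    Y <- as.matrix(read.csv(config$y_csv))
    colnames(Y) <- NULL
    geometry <- NULL
  }
  if (nrow(Y) != nrow(design) || length(mdi) != nrow(design)) {
    abort("subject counts of maps, design and MDI table do not match.")
  }
  list(Y = Y, X = build_design(design), design = design, mdi = mdi,
       geometry = geometry)
}

#' Run the full analysis pipeline
#'
#' Executes, from one config: map loading (or simulation, or R2*/MDI
#' computation from raw echoes), REML noise estimation with the configured
#' MDI powers, OLS and WLS model fits, the F test of the configured contrast
#' with voxel-level (and optionally cluster-level) familywise-error control,
#' and heteroscedasticity diagnostics for both fits. All randomness flows
#' from `config$seed`.
#'
#' @param config a [quiqi_config()] (list or YAML path).
#' @return invisibly, a list with the fitted objects (`reml`, `fit_ols`,
#'   `fit_wls`, `statmap`, `sig_voxels`, `clusters`, `diag_ols`, `diag_wls`)
#'   and `report` (the machine-readable summary). When `config$out_dir` is
#'   set, writes `report.json`, `weights.csv`, `var_eps.csv`, `statmap.csv`,
#'   `clusters.csv` and (for grid data) NIfTI stat maps into it.
#' @export
quiqi_run <- function(config) {
  config <- quiqi_config(config)
  dat <- load_pipeline_data(config)
  contrast <- intersect(config$contrast, colnames(dat$X))
  if (length(contrast) == 0) abort("no contrast column present in the design.")

  reml <- reml_estimate(dat$Y, dat$X, build_basis(dat$mdi, config$powers),
                        positivity = config$positivity)
  fit_ols <- fit_glm(dat$Y, dat$X)
  fit_wls <- fit_glm(dat$Y, dat$X, weights = reml$w)
  map <- f_test(fit_wls, contrast)
  attr(map, "geometry") <- dat$geometry
  sig <- fwe_voxel(map, config$alpha)
  clusters <- NULL
  if (isTRUE(config$cluster) && !is.null(dat$geometry)) {
    clusters <- cluster_inference(dat$Y, dat$X, contrast, dat$geometry,
                                  weights = reml$w, cft_p = config$cft_p,
                                  n_perm = config$n_perm, seed = config$seed)
  }
  diag_ols <- diagnose(fit_ols, dat$mdi, order = config$order)
  diag_wls <- diagnose(fit_wls, dat$mdi, order = config$order)

  report <- list(
    provenance = list(package = "quiqir",
                      version = as.character(utils::packageVersion("quiqir")),
                      r_version = R.version.string,
                      seed = config$seed,
                      powers = config$powers,
                      positivity = config$positivity,
                      contrast = contrast,
                      alpha = config$alpha,
                      timestamp = format(Sys.time(), tz = "UTC")),
    n_subjects = nrow(dat$Y), n_voxels = ncol(dat$Y),
    lambdas = as.list(reml$lambdas), elbo = reml$elbo,
    reml_converged = reml$converged,
    hetero_r2_ols = diag_ols$r2_poly, hetero_r2_wls = diag_wls$r2_poly,
    frac_arch_sig_ols = diag_ols$frac_arch_sig,
    frac_arch_sig_wls = diag_wls$frac_arch_sig,
    n_sig_voxels = nrow(sig),
    n_sig_clusters = if (!is.null(clusters)) {
      sum(clusters$p_fwe <= config$alpha)
    } else NA
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(data.frame(subject = seq_along(reml$w), v = reml$v, w = reml$w),
              file.path(config$out_dir, "weights.csv"), row.names = FALSE)
    write.csv(dplyr::left_join(tidy(diag_ols),
                               dplyr::rename(tidy(diag_wls),
                                             var_eps_wls = "var_eps"),
                               by = c("subject", "mdi")),
              file.path(config$out_dir, "var_eps.csv"), row.names = FALSE)
    write.csv(as.data.frame(map), file.path(config$out_dir, "statmap.csv"),
              row.names = FALSE)
    if (!is.null(clusters)) {
      write.csv(as.data.frame(dplyr::select(clusters, -dplyr::any_of("sig_voxels"))),
                file.path(config$out_dir, "clusters.csv"), row.names = FALSE)
    }
    if (!is.null(dat$geometry)) {
      write_statmap(map, file.path(config$out_dir, "fmap.nii.gz"))
    }
  }
  invisible(list(reml = reml, fit_ols = fit_ols, fit_wls = fit_wls,
                 statmap = map, sig_voxels = sig, clusters = clusters,
                 diag_ols = diag_ols, diag_wls = diag_wls, report = report))
}

#' Noise-vs-MDI quality check
#'
#' Computes, independently of any inference, the per-subject residual
#' spatial variance against the MDI with an order-`order` polynomial fit and
#' its R-squared, for the OLS fit and (when weights are supplied) the WLS
#' fit. The polynomial fits are descriptive only; they are never fed back
#' into the analysis.
#'
#' @param Y subjects x voxels matrix, or a `quiqir_cohort`.
#' @param X design matrix (taken from the cohort if omitted).
#' @param mdi per-subject MDI values (taken from the cohort if omitted).
#' @param weights optional WLS weights (vector or `quiqir_reml` fit).
#' @param order polynomial order (default 3).
#' @param mask optional voxel mask.
#' @return a `quiqir_check` object: `data` (tibble: subject, mdi,
#'   var_eps_ols[, var_eps_wls]), `curves`, `r2_ols`, `r2_wls` (NA without
#'   weights). Has an [autoplot()] method.
#' @export
quiqi_check <- function(Y, X = NULL, mdi = NULL, weights = NULL, order = 3,
                        mask = NULL) {
  if (inherits(Y, "quiqir_cohort")) {
    X <- X %||% Y$X
    mdi <- mdi %||% Y$mdi
    Y <- Y$Y
  }
  fit_ols <- fit_glm(Y, X)
  ve_ols <- residual_spatial_variance(fit_ols, mask)
  hr_ols <- hetero_r2(ve_ols$var_eps, mdi, order)
  data <- tibble(subject = ve_ols$subject, mdi = as.numeric(mdi),
                 var_eps_ols = ve_ols$var_eps)
  grid <- seq(min(mdi), max(mdi), length.out = 200)
  pows <- outer(grid, 0:order, `^`)
  curves <- tibble(mdi = grid, fit_ols = drop(pows %*% hr_ols$coefficients))
  r2_wls <- NA_real_
  if (!is.null(weights)) {
    fit_wls <- fit_glm(Y, X, weights)
    ve_wls <- residual_spatial_variance(fit_wls, mask)
    hr_wls <- hetero_r2(ve_wls$var_eps, mdi, order)
    data$var_eps_wls <- ve_wls$var_eps
    curves$fit_wls <- drop(pows %*% hr_wls$coefficients)
    r2_wls <- hr_wls$r2
  }
  structure(list(data = data, curves = curves, r2_ols = hr_ols$r2,
                 r2_wls = r2_wls, order = order),
            class = "quiqir_check")
}

#' @export
print.quiqir_check <- function(x, ...) {
  cat(sprintf("<quiqir_check> order-%d polynomial fit of var[eps] vs MDI\n",
              x$order))
  cat(sprintf("  OLS R^2: %.3f", x$r2_ols))
  if (!is.na(x$r2_wls)) cat(sprintf("   WLS R^2: %.3f", x$r2_wls))
  cat("\n")
  invisible(x)
}
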