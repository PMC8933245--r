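#' Specify a synthetic cohort
#'
#' Builds the specification for a seeded synthetic cohort of quantitative-map
#' "images" with a per-subject motion degradation index (MDI) and noise whose
#' variance is a polynomial in the MDI: `Var(eps_j) = sum_i lambda_i * MDI_j^alpha_i`.
#' This is the data model the weighted analysis assumes, so cohorts generated
#' from it support parameter-recovery and calibration experiments for every
#' other component of the package.
#'
#' @param n_subjects number of subjects (images).
#' @param n_voxels number of voxels per image; ignored when `grid_dim` is given.
#' @param grid_dim optional integer vector of length 3; when supplied the
#'   voxels form a 3D grid (geometry is retained so cluster-level inference and
#'   NIfTI export are possible) and `n_voxels = prod(grid_dim)`.
#' @param mdi list describing the MDI distribution. Default is a right-skewed
#'   offset gamma: `shape`, `scale`, `offset`, `multiplier` (values are
#'   `multiplier * (rgamma(shape, scale) + offset)`, in s^-1).
#' @param design list of covariate distributions: `age_range` (uniform, years),
#'   `sex_p` (probability of sex = 1), `volume_mean`, `volume_sd` (brain
#'   volume, ml).
#' @param noise list with `lambdas` and `powers` defining the per-subject noise
#'   variance polynomial in the MDI. Default `lambdas = 1`, `powers = 0`
#'   (homoscedastic, unit variance).
#' @param effects list describing true age effects: `active_frac` (fraction of
#'   voxels with a nonzero age slope), `beta_age` (slope per year, recycled or
#'   a range via `beta_age_range`), `beta_age2` (quadratic term), `layout`
#'   ("scatter" places active voxels at random; "block" places a contiguous
#'   cube, only for grid cohorts).
#' @param smooth_fwhm optional spatial smoothing FWHM (in voxels) applied to
#'   the noise field of grid cohorts; the field's variance is renormalised
#'   after smoothing so per-subject variances are preserved.
#' @param seed integer seed; identical spec + seed gives identical cohorts.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 200,
                        n_voxels = 2000,
                        grid_dim = NULL,
                        mdi = list(),
                        design = list(),
                        noise = list(),
                        effects = list(),
                        smooth_fwhm = NULL,
                        seed = 1L) {
  mdi <- utils::modifyList(
    list(shape = 2, scale = 1, offset = 0.5, multiplier = 1), mdi
  )
  design <- utils::modifyList(
    list(age_range = c(20, 80), sex_p = 0.5, volume_mean = 1400, volume_sd = 130),
    design
  )
  noise <- utils::modifyList(list(lambdas = 1, powers = 0), noise)
  effects <- utils::modifyList(
    list(active_frac = 0, beta_age = 0.02, beta_age_range = NULL,
         beta_age2 = 0, layout = "scatter"),
    effects
  )
  if (!is.null(grid_dim)) {
    grid_dim <- as.integer(grid_dim)
    stopifnot(length(grid_dim) == 3, all(grid_dim >= 1))
    n_voxels <- prod(grid_dim)
  }
  if (length(noise$lambdas) != length(noise$powers)) {
    abort("`noise$lambdas` and `noise$powers` must have the same length.")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_voxels = as.integer(n_voxels),
         grid_dim = grid_dim, mdi = mdi, design = design, noise = noise,
         effects = effects, smooth_fwhm = smooth_fwhm, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]: per-subject MDI values, covariates
#' (age, age squared, sex, brain volume), voxel data `Y = X beta + eps` with
#' `eps_j ~ N(0, sum_i lambda_i MDI_j^alpha_i)` independently across subjects,
#' and a truth record for parameter-recovery checks.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `quiqir_cohort`: a list with elements
#'   `Y` (subjects x voxels matrix), `design` (tibble of raw covariates),
#'   `X` (design matrix with named columns: intercept, centred age, centred
#'   age squared, sex, centred volume), `mdi` (numeric vector, s^-1),
#'   `geometry` (voxel grid info or `NULL`), and `truth` (true betas, lambdas,
#'   powers, active voxel indices, seed).
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 40, n_voxels = 100, seed = 7))
#' dim(co$Y)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  v <- spec$n_voxels
  with_seed(spec$seed, {
    mdi <- spec$mdi$multiplier *
      (rgamma(n, shape = spec$mdi$shape, scale = spec$mdi$scale) + spec$mdi$offset)
    age <- runif(n, spec$design$age_range[1], spec$design$age_range[2])
    sex <- rbinom(n, 1, spec$design$sex_p)
    volume <- rnorm(n, spec$design$volume_mean, spec$design$volume_sd)
    design <- tibble(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      age = age, sex = sex, volume = volume
    )
    X <- build_design(design)

    var_j <- noise_variance(mdi, spec$noise$lambdas, spec$noise$powers)
    if (any(!is.finite(var_j)) || any(var_j <= 0)) {
      abort("noise specification gives non-positive variance for some subject.")
    }

    n_active <- ceiling(spec$effects$active_frac * v)
    active <- integer(0)
    beta <- matrix(0, ncol(X), v, dimnames = list(colnames(X), NULL))
    if (n_active > 0) {
      active <- pick_active(spec, n_active)
      ba <- if (!is.null(spec$effects$beta_age_range)) {
        seq(spec$effects$beta_age_range[1], spec$effects$beta_age_range[2],
            length.out = n_active)
      } else rep_len(spec$effects$beta_age, n_active)
      beta["age", active] <- ba
      beta["age2", active] <- rep_len(spec$effects$beta_age2, n_active)
    }

    eps <- matrix(rnorm(n * v), n, v)
    if (!is.null(spec$smooth_fwhm) && !is.null(spec$grid_dim)) {
      sigma <- spec$smooth_fwhm / (2 * sqrt(2 * log(2)))
      for (j in seq_len(n)) {
        f <- smooth3d(array(eps[j, ], spec$grid_dim), sigma)
        eps[j, ] <- as.vector(f) / stats::sd(as.vector(f))
      }
    }
    Y <- X %*% beta + eps * sqrt(var_j)

    geometry <- if (!is.null(spec$grid_dim)) {
      list(dim = spec$grid_dim,
           coords = as.matrix(expand.grid(
             x = seq_len(spec$grid_dim[1]),
             y = seq_len(spec$grid_dim[2]),
             z = seq_len(spec$grid_dim[3]))))
    }
    structure(
      list(Y = unname(Y), design = design, X = X, mdi = mdi,
           geometry = geometry,
           truth = list(beta = beta, lambdas = spec$noise$lambdas,
                        powers = spec$noise$powers, active = active,
                        var_subject = var_j, seed = spec$seed)),
      class = "quiqir_cohort"
    )
  })
}

noise_variance <- function(mdi, lambdas, powers) {
  Q <- outer(mdi, powers, `^`)
  drop(Q %*% lambdas)
}

pick_active <- function(spec, n_active) {
  v <- spec$n_voxels
  if (identical(spec$effects$layout, "block") && !is.null(spec$grid_dim)) {
    side <- ceiling(n_active^(1 / 3))
    g <- spec$grid_dim
    side <- min(side, min(g))
    arr <- array(seq_len(v), g)
    idx <- as.vector(arr[seq_len(side), seq_len(side), seq_len(side)])
    sort(idx[seq_len(min(n_active, length(idx)))])
  } else {
    sort(sample.int(v, n_active))
  }
}

#' Build the standard design matrix from a covariate table
#'
#' Columns: intercept, mean-centred age, centred squared centred age, sex
#' (0/1), mean-centred brain volume. Centring keeps the design well
#' conditioned; joint F tests of the age columns are unaffected by it.
#'
#' @param design data frame with columns `age`, `sex`, `volume`.
#' @param age_squared include the quadratic age column (default `TRUE`).
#' @return numeric design matrix with named columns.
#' @export
build_design <- function(design, age_squared = TRUE) {
  age_c <- design$age - mean(design$age)
  cols <- list(intercept = rep(1, nrow(design)), age = age_c)
  if (age_squared) {
    a2 <- age_c^2
    cols$age2 <- a2 - mean(a2)
  }
  cols$sex <- as.numeric(design$sex)
  cols$volume <- design$volume - mean(design$volume)
  X <- do.call(cbind, cols)
  check_design(X, nrow(design))
}

# Separable 3D Gaussian smoothing with edge renormalisation.
smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  ones <- array(1, dim(arr))
  num <- conv_axis(conv_axis(conv_axis(arr, k, 1), k, 2), k, 3)
  den <- conv_axis(conv_axis(conv_axis(ones, k, 1), k, 2), k, 3)
  num / den
}

# Convolve a 3D array with kernel k along one axis (zero padding).
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  half <- (length(k) - 1L) / 2L
  out <- array(0, d)
  for (s in seq_along(k)) {
    off <- s - half - 1L
    src <- pmin(pmax(seq_len(d[axis]) + off, 0L), d[axis] + 1L)
    valid <- src >= 1L & src <= d[axis]
    idx_out <- which(valid)
    idx_src <- src[valid]
    if (axis == 1) out[idx_out, , ] <- out[idx_out, , ] + k[s] * arr[idx_src, , ]
    if (axis == 2) out[, idx_out, ] <- out[, idx_out, ] + k[s] * arr[, idx_src, ]
    if (axis == 3) out[, , idx_out] <- out[, , idx_out] + k[s] * arr[, , idx_src]
  }
  out
}

#' Generate a synthetic multi-echo gradient-echo series
#'
#' Produces magnitude images `S(TE) = S0 * exp(-R2* * TE)` plus noise, for
#' exercising the R2* log-linear fit. `noise = "rician"` forms the magnitude
#' of a complex Gaussian around the noiseless signal, the realistic model for
#' magnitude MRI.
#'
#' @param r2star_truth 3D array of true R2* (s^-1).
#' @param s0 3D array of true signal amplitude (arbitrary units, positive).
#' @param echo_times strictly increasing echo times in ms.
#' @param noise_sd additive noise standard deviation (same units as `s0`).
#' @param seed integer seed.
#' @param noise "gaussian" or "rician".
#' @return a `multi_echo` object: list with `volumes` (4D array x,y,z,echo)
#'   and `echo_times` (ms).
#' @export
generate_multi_echo <- function(r2star_truth, s0, echo_times, noise_sd = 0,
                                seed = 1L, noise = c("gaussian", "rician")) {
  noise <- match.arg(noise)
  r2star_truth <- as.array(r2star_truth)
  s0 <- as.array(s0)
  stopifnot(identical(dim(r2star_truth), dim(s0)))
  if (any(s0 < 0)) abort("`s0` must be non-negative.")
  if (is.unsorted(echo_times, strictly = TRUE) || any(echo_times <= 0)) {
    abort("`echo_times` must be strictly increasing and positive (ms).")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  d <- dim(r2star_truth)
  ne <- length(echo_times)
  vol <- array(0, c(d, ne))
  with_seed(seed, {
    for (e in seq_len(ne)) {
      s <- s0 * exp(-(r2star_truth / 1000) * echo_times[e])
      if (noise_sd == 0) {
        vol[, , , e] <- s
      } else if (noise == "gaussian") {
        vol[, , , e] <- s + rnorm(length(s), sd = noise_sd)
      } else {
        re <- s + rnorm(length(s), sd = noise_sd)
        im <- rnorm(length(s), sd = noise_sd)
        vol[, , , e] <- sqrt(re^2 + im^2)
      }
    }
  })
  multi_echo(vol, echo_times)
}

#' Construct a multi-echo series object
#'
#' @param volumes 4D non-negative array (x, y, z, echo).
#' @param echo_times strictly increasing echo times, ms, one per 4th-dim slab.
#' @return a `multi_echo` object.
#' @export
multi_echo <- function(volumes, echo_times) {
  volumes <- as.array(volumes)
  if (length(dim(volumes)) != 4) abort("`volumes` must be a 4D array (x,y,z,echo).")
  if (dim(volumes)[4] < 2) abort("at least 2 echoes are required.")
  if (length(echo_times) != dim(volumes)[4]) {
    abort("`echo_times` length must equal the number of echoes.")
  }
  if (is.unsorted(echo_times, strictly = TRUE) || any(echo_times <= 0)) {
    abort("`echo_times` must be strictly increasing and positive (ms).")
  }
  structure(list(volumes = volumes, echo_times = as.numeric(echo_times)),
            class = "multi_echo")
}

#' Export a synthetic cohort to disk
#'
#' Writes one NIfTI volume per subject (grid cohorts) or a `y.csv` matrix
#' (flat cohorts), plus `design.csv`, `mdi.csv` and `truth.json`. The layout
#' round-trips losslessly (to float32 NIfTI precision) through
#' [read_cohort()].
#'
#' @param cohort a `quiqir_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "quiqir_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'.", dir))
  n <- nrow(cohort$Y)
  if (!is.null(cohort$geometry)) {
    for (j in seq_len(n)) {
      img <- array(cohort$Y[j, ], cohort$geometry$dim)
      RNifti::writeNifti(RNifti::asNifti(img, datatype = "float"),
                         file.path(dir, sprintf("%s_map.nii.gz",
                                                cohort$design$subject_id[j])))
    }
  } else {
    write.csv(as.data.frame(cohort$Y), file.path(dir, "y.csv"), row.names = FALSE)
  }
  write.csv(cohort$design, file.path(dir, "design.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = cohort$design$subject_id,
                       mdi = cohort$mdi),
            file.path(dir, "mdi.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$beta <- NULL  # dense p x V matrix; active slopes suffice to rebuild it
  truth$beta_age_active <- unname(cohort$truth$beta["age", cohort$truth$active])
  truth$beta_age2_active <- unname(cohort$truth$beta["age2", cohort$truth$active])
  extra <- list(n_subjects = n, n_voxels = ncol(cohort$Y))
  if (!is.null(cohort$geometry)) extra$grid_dim <- cohort$geometry$dim
  jsonlite::write_json(c(truth, extra), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort exported by [export_cohort()]
#'
#' @param dir directory written by [export_cohort()].
#' @return a `quiqir_cohort` (the `truth` element is the re-read JSON record).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("directory '%s' not found.", dir))
  design <- as_tibble(read.csv(file.path(dir, "design.csv")))
  mdi_tbl <- read.csv(file.path(dir, "mdi.csv"))
  if (!identical(as.character(mdi_tbl$subject_id), as.character(design$subject_id))) {
    abort("subject ids in mdi.csv do not match design.csv.")
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  geometry <- NULL
  if (length(truth$grid_dim) == 3) {
    gd <- as.integer(truth$grid_dim)
    files <- file.path(dir, sprintf("%s_map.nii.gz", design$subject_id))
    missing <- !file.exists(files)
    if (any(missing)) {
      abort(sprintf("missing map volume(s): %s",
                    paste(basename(files[missing]), collapse = ", ")))
    }
    Y <- t(vapply(files, function(f) as.vector(RNifti::readNifti(f)),
                  numeric(prod(gd))))
    rownames(Y) <- NULL
    geometry <- list(dim = gd,
                     coords = as.matrix(expand.grid(x = seq_len(gd[1]),
                                                    y = seq_len(gd[2]),
                                                    z = seq_len(gd[3]))))
  } else {
    Y <- as.matrix(read.csv(file.path(dir, "y.csv")))
    colnames(Y) <- NULL
    if (nrow(Y) != nrow(design)) {
      abort("subject count in y.csv does not match design.csv.")
    }
  }
  if (nrow(Y) != nrow(design)) abort("subject count mismatch between maps and design.")
  structure(list(Y = Y, design = design, X = build_design(design),
                 mdi = mdi_tbl$mdi, geometry = geometry, truth = truth),
            class = "quiqir_cohort")
}

#' @export
print.quiqir_cohort <- function(x, ...) {
  cat(sprintf("<quiqir_cohort> %d subjects x %d voxels%s\n",
              nrow(x$Y), ncol(x$Y),
              if (!is.null(x$geometry))
                sprintf(" (grid %s)", paste(x$geometry$dim, collapse = "x"))
              else ""))
  cat(sprintf("  MDI: mean %.3f, range [%.3f, %.3f] s^-1\n",
              mean(x$mdi), min(x$mdi), max(x$mdi)))
  cat(sprintf("  noise powers: {%s}, active voxels: %d\n",
              paste(x$truth$powers, collapse = ", "),
              length(x$truth$active)))
  invisible(x)
}
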