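#' Fit an R2* map from multi-echo magnitude data
#'
#' Estimates the effective transverse relaxation rate R2* in every masked
#' voxel by ordinary least squares on the log signal: for a mono-exponential
#' decay `S(TE) = S0 exp(-R2* TE)`, the slope of `ln S` against echo time is
#' `-R2*`. Echo times are in ms; the returned map is in s^-1. Voxels with any
#' non-positive echo signal (where the log is undefined) are dropped from the
#' mask with a warning rather than clipped, keeping the log-linear model
#' exact.
#'
#' @param series a [multi_echo()] object.
#' @param mask 3D logical array of voxels to fit; default all voxels.
#' @return a `qmap` object: list with `values` (3D array of R2*, s^-1; `NA`
#'   outside the mask), `s0` (amplitude estimates, same layout), and `mask`
#'   (3D logical of voxels actually fitted).
#' @examples
#' te <- seq(2.34, by = 2.34, length.out = 6)
#' s <- generate_multi_echo(array(20, c(2, 2, 2)), array(100, c(2, 2, 2)), te)
#' fit_r2star(s)$values[1, 1, 1]
#' @export
fit_r2star <- function(series, mask = NULL) {
  stopifnot(inherits(series, "multi_echo"))
  d <- dim(series$volumes)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- binarise_mask(mask, d)
  if (!any(mask)) abort("mask is empty.")

  ne <- length(series$echo_times)
  sig <- matrix(series$volumes, prod(d), ne)[as.vector(mask), , drop = FALSE]
  bad <- rowSums(sig <= 0) > 0
  if (any(bad)) {
    warn(sprintf("%d voxel(s) with non-positive signal excluded from the mask.",
                 sum(bad)))
  }
  usable <- which(as.vector(mask))[!bad]
  values <- array(NA_real_, d)
  s0 <- array(NA_real_, d)
  out_mask <- array(FALSE, d)
  if (length(usable)) {
    L <- log(sig[!bad, , drop = FALSE])
    te <- series$echo_times
    tc <- te - mean(te)
    slope <- (L %*% tc) / sum(tc^2)           # per-voxel OLS slope, per ms
    intercept <- rowMeans(L) - slope * mean(te)
    values[usable] <- -slope * 1000           # ms^-1 -> s^-1
    s0[usable] <- exp(intercept)
    out_mask[usable] <- TRUE
  }
  structure(list(values = values, s0 = s0, mask = out_mask), class = "qmap")
}

#' Compute the motion degradation index from an R2* map
#'
#' The MDI is the standard deviation of R2* within white matter: head motion
#' blurs the sharp R2* contrast of white matter, inflating its spread, which
#' makes this a per-image quality score (validated elsewhere against tracked
#' head motion). The sample standard deviation (divisor n-1) is used.
#'
#' @param r2star a `qmap` from [fit_r2star()], or a 3D numeric array.
#' @param wm_mask 3D white-matter mask: logical, or probabilistic (binarised
#'   at `threshold`).
#' @param threshold binarisation threshold for probabilistic masks.
#' @return a tibble with one row: `mdi` (s^-1) and `n_voxels` used.
#' @export
compute_mdi <- function(r2star, wm_mask, threshold = 0.5) {
  if (inherits(r2star, "qmap")) {
    vals <- r2star$values
    valid <- r2star$mask
  } else {
    vals <- as.array(r2star)
    valid <- is.finite(vals)
  }
  wm <- binarise_mask(wm_mask, dim(vals), threshold)
  use <- wm & valid
  n <- sum(use)
  if (n < 2) abort("fewer than 2 usable white-matter voxels; cannot compute MDI.")
  tibble(mdi = stats::sd(vals[use]), n_voxels = n)
}

binarise_mask <- function(mask, d, threshold = 0.5) {
  mask <- as.array(mask)
  if (!identical(as.integer(dim(mask)), as.integer(d))) {
    abort("mask dimensions do not match the image.")
  }
  if (is.logical(mask)) return(mask)
  mask > threshold
}

#' Read a multi-echo series from NIfTI files
#'
#' @param paths one 4D NIfTI path or a vector of 3D paths, one per echo.
#' @param echo_times echo times in ms, or a path to a JSON/YAML sidecar with
#'   an `EchoTimes` field (ms).
#' @return a [multi_echo()] object.
#' @export
read_multi_echo <- function(paths, echo_times) {
  if (is.character(echo_times) && length(echo_times) == 1) {
    side <- if (grepl("\\.json$", echo_times)) {
      jsonlite::read_json(echo_times, simplifyVector = TRUE)
    } else yaml::read_yaml(echo_times)
    echo_times <- side$EchoTimes %||% side$echo_times
    if (is.null(echo_times)) abort("sidecar has no EchoTimes field.")
  }
  if (length(paths) == 1) {
    vol <- as.array(RNifti::readNifti(paths))
    if (length(dim(vol)) != 4) abort("single-file input must be a 4D NIfTI.")
  } else {
    vols <- lapply(paths, function(p) as.array(RNifti::readNifti(p)))
    vol <- array(unlist(vols), c(dim(vols[[1]]), length(vols)))
  }
  multi_echo(vol, as.numeric(echo_times))
}

#' Read a 3D NIfTI mask
#'
#' @param path NIfTI file.
#' @param threshold binarisation threshold for probabilistic masks.
#' @return 3D logical array.
#' @export
read_mask <- function(path, threshold = 0.5) {
  m <- as.array(RNifti::readNifti(path))
  binarise_mask(m, dim(m), threshold)
}

#' Write a qmap (or any 3D array) as NIfTI
#'
#' @param map a `qmap` or 3D array.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_qmap <- function(map, path) {
  vals <- if (inherits(map, "qmap")) map$values else as.array(map)
  RNifti::writeNifti(RNifti::asNifti(vals, datatype = "float"), path)
  invisible(path)
}

#' @export
print.qmap <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<qmap> %s, %d masked voxels, R2* median %.2f s^-1\n",
              paste(dim(x$values), collapse = "x"), sum(x$mask),
              stats::median(v)))
  invisible(x)
}
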