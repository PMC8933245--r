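# ggplot2 visualisations

#' Plot the noise-vs-MDI diagnostics ("quality check" plot)
#'
#' Scatter of per-subject residual spatial variance against the MDI, with
#' the fitted polynomial curve and its R-squared. A flat cloud (R^2 near 0)
#' indicates homoscedastic residuals.
#'
#' @param object a `quiqir_diagnostics` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.quiqir_diagnostics <- function(object, ...) {
  d <- object$var_eps
  grid <- tibble(mdi = seq(min(d$mdi), max(d$mdi), length.out = 200))
  grid$fit <- drop(outer(grid$mdi, seq_along(object$poly_coefficients) - 1, `^`) %*%
                     object$poly_coefficients)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mdi, y = .data$var_eps)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = expression(MDI ~ (s^-1)), y = expression(var[epsilon]),
      title = sprintf("%s residual noise vs MDI",
                      if (object$weighted) "Whitened (WLS)" else "OLS"),
      subtitle = sprintf("order-%d polynomial fit, R² = %.3f",
                         object$order, object$r2_poly)) +
    ggplot2::theme_minimal()
}

#' Plot a REML convergence trace
#'
#' @param object a `quiqir_reml` object.
#' @param ... unused.
#' @return a ggplot of the accepted ELBO values per iteration.
#' @export
autoplot.quiqir_reml <- function(object, ...) {
  d <- tibble(iteration = seq_along(object$trace) - 1, elbo = object$trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$elbo)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "iteration", y = "ELBO",
                  title = sprintf("REML ascent, powers {%s}",
                                  paste(object$powers, collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Plot a statistic map summary
#'
#' Histogram of the voxel-wise statistics with the p-value distribution as a
#' second panel would require patchwork; a single histogram keeps the
#' dependency footprint small.
#'
#' @param object a `quiqir_statmap`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.quiqir_statmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::labs(x = sprintf("%s statistic (%s)", attr(object, "type"),
                              attr(object, "contrast")),
                  y = "voxels") +
    ggplot2::theme_minimal()
}

#' Plot a noise-model comparison (quality check, OLS vs WLS)
#'
#' @param object a `quiqir_check` object from [quiqi_check()].
#' @param ... unused.
#' @return a ggplot with one facet per analysis mode.
#' @export
autoplot.quiqir_check <- function(object, ...) {
  d <- tidyr::pivot_longer(object$data, dplyr::starts_with("var_eps"),
                           names_to = "mode", values_to = "var_eps",
                           names_prefix = "var_eps_")
  d$mode <- toupper(d$mode)
  curves <- tidyr::pivot_longer(object$curves, dplyr::starts_with("fit"),
                                names_to = "mode", values_to = "fit",
                                names_prefix = "fit_")
  curves$mode <- toupper(curves$mode)
  labs <- vapply(unique(d$mode), function(m) {
    sprintf("%s (R² = %.3f)", m,
            if (m == "OLS") object$r2_ols else object$r2_wls)
  }, character(1))
  d$panel <- labs[d$mode]; curves$panel <- labs[curves$mode]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mdi, y = .data$var_eps)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = expression(MDI ~ (s^-1)), y = expression(var[epsilon])) +
    ggplot2::theme_minimal()
}
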