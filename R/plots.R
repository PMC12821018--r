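#' Plot a force curve
#'
#' Force (or deflection) against piezo height, coloured by segment.
#'
#' @param object A [force_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot force_curve
#' @export
autoplot.force_curve <- function(object, ...) {
  calibrated <- object$calibrated
  dat <- object$data
  if (calibrated) {
    ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$height_m * 1e6, y = .data$force_n * 1e9,
      colour = .data$segment)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = "piezo height (um)", y = "force (nN)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$height_m * 1e6, y = .data$deflection_m * 1e9,
      colour = .data$segment)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = "piezo height (um)", y = "deflection (nm)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot an elasticity map
#'
#' Map positions coloured by K, shaped by compartment.
#'
#' @param object An `elasticity_map` from [as_elasticity_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot elasticity_map
#' @export
autoplot.elasticity_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$x_um, y = .data$y_um, colour = .data$K_pa,
    shape = .data$label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_viridis_c(name = "K (Pa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the linear-vs-horizontal model comparison
#'
#' Data points with both fitted models overlaid; the preferred model is
#' drawn solid.
#'
#' @param object A `model_comparison` from [fit_linear_vs_constant()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  lin_pref <- object$preferred == "linear"
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = if (lin_pref) "solid" else "dashed") +
    ggplot2::geom_hline(yintercept = object$constant,
                        linetype = if (lin_pref) "dashed" else "solid") +
    ggplot2::labs(x = object$x_name, y = object$y_name,
                  subtitle = sprintf("F = %.3g, p = %.3g, preferred: %s",
                                     object$f_statistic, object$p_value,
                                     object$preferred)) +
    ggplot2::theme_minimal()
}

#' Plot a binned postmortem series
#'
#' Per-bin mean with SD error bars.
#'
#' @param binned Output of [bin_timeseries()].
#' @return A ggplot.
#' @export
plot_binned_series <- function(binned) {
  dat <- binned[!binned$underflow, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_mid_h, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = "time postmortem (h)", y = "mean per bin") +
    ggplot2::theme_minimal()
}
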