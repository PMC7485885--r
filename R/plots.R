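#' Plot a pen recording's trace
#'
#' Pen-down trace in mm, coloured by pressure, with hover positions shown
#' faintly. The y axis is flipped to match the screen convention (y grows
#' downward).
#'
#' @param object A [pen_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pen_recording
#' @export
autoplot.pen_recording <- function(object, ...) {
  res <- rec_resolution(object)
  df <- tibble::tibble(x = object$x * res, y = object$y * res,
                       pressure = object$pressure,
                       on_surface = object$on_surface)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(data = df[!df$on_surface, ], colour = "grey80",
                        size = 0.3) +
    ggplot2::geom_point(data = df[df$on_surface, ],
                        ggplot2::aes(colour = .data$pressure), size = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "pressure") +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object A [power_spectrum()].
#' @param ... Unused.
#' @return A ggplot of normalized power against frequency, with the
#'   spectral median marked.
#' @method autoplot hw_power_spectrum
#' @export
autoplot.hw_power_spectrum <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$freq, .data$normalized_power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power") +
    ggplot2::theme_minimal()
  if (!spectrum_degenerate(object)) {
    p <- p + ggplot2::geom_vline(xintercept = spectral_median(object),
                                 linetype = "dashed", colour = "red3")
  }
  p
}

#' Plot a clustering result
#'
#' Children in the plane of the first two principal components of the
#' standardized feature matrix, coloured by cluster.
#'
#' @param object A [subtype_clustering()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hw_cluster_result
#' @export
autoplot.hw_cluster_result <- function(object, ...) {
  pc <- stats::prcomp(object$matrix)
  df <- tibble::tibble(pc1 = pc$x[, 1], pc2 = pc$x[, 2],
                       cluster = factor(object$assignments[
                         object$used_rows]))
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = sprintf("k = %d, Hopkins = %.2f", object$k,
                                  object$hopkins)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a model battery
#'
#' Point estimates with bootstrap 95% intervals per feature, faceted by
#' outcome and model form.
#'
#' @param battery Output of [run_model_battery()].
#' @return A ggplot.
#' @export
plot_model_battery <- function(battery) {
  ggplot2::ggplot(battery,
                  ggplot2::aes(.data$estimate, .data$feature,
                               colour = .data$dataset)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(ggplot2::vars(.data$form),
                        ggplot2::vars(.data$outcome), scales = "free_x") +
    ggplot2::labs(x = "estimate (per SD of feature)", y = NULL) +
    ggplot2::theme_minimal()
}
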