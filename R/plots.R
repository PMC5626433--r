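#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster layer
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- raster_cells(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "value") +
    ggplot2::theme_minimal()
}

#' Plot a residual correlogram
#'
#' Per-bin autocorrelation against distance, with significant bins
#' (permutation p below `alpha`) highlighted and, when at least four bins
#' are available, the weighted spline smooth overlaid.
#'
#' @param object A [residual_correlogram()] result.
#' @param alpha Significance level for highlighting (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlogram <- function(object, alpha = 0.05, ...) {
  b <- dplyr::mutate(object$bins, significant = .data$p_perm < alpha)
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$bin_center, y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant,
                                     size = .data$n_pairs)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "distance (m)", y = "autocorrelation",
                  colour = sprintf("p < %g", alpha), size = "pairs") +
    ggplot2::theme_minimal()
  if (nrow(object$bins) >= 4) {
    sm <- spline_smooth(object)
    p <- p + ggplot2::geom_line(data = sm$curve,
                                ggplot2::aes(x = .data$distance,
                                             y = .data$rho_hat),
                                colour = "steelblue")
  }
  p
}

#' Forest plot of model-averaged estimates
#'
#' Averaged estimates of the scaled test predictors with plus/minus two
#' unconditional SDs, sized by relative importance.
#'
#' @param object A [fit_texture_model()] result (or an `averaged_model`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bee_texture_model <- function(object, ...) {
  d <- object$averaged
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term,
                                                     .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$estimate - 2 * .data$sd,
                                         xmax = .data$estimate + 2 * .data$sd),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$importance),
                        colour = "steelblue") +
    ggplot2::labs(x = "model-averaged estimate (per SD of predictor)",
                  y = NULL, size = "importance",
                  title = sprintf("Response: %s (%d models averaged)",
                                  object$response, object$n_model)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.averaged_model <- function(object, ...) {
  autoplot.bee_texture_model(list(averaged = object$coefficients,
                                  response = object$response,
                                  n_model = object$n_model))
}
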