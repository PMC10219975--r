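# ggplot2 autoplot methods for result objects.

#' Plot an attenuation fit
#'
#' Depth-bin median intensities on a log scale with the fitted
#' Beer-Lambert exponential and the 1/e depth marked.
#'
#' @param object an `attenuation_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.attenuation_fit <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_um,
                                        y = .data$median_intensity)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "depth below block face (µm)",
                  y = "median cell intensity (DN)",
                  size = "cells/bin") +
    ggplot2::theme_minimal()
  if (!object$failed) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "magenta") +
      ggplot2::geom_vline(xintercept = object$d_hat_um,
                          linetype = "dashed") +
      ggplot2::ggtitle(sprintf("1/e depth = %.1f µm (R² = %.3f)",
                               object$d_hat_um, object$r_squared))
  }
  p
}

#' Plot a depth-correlation profile
#'
#' @param object a `depth_correlation` tibble.
#' @param ... unused.
#' @return A ggplot of Pearson r against slice depth.
#' @export
autoplot.depth_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_um, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "slice depth (µm)",
                  y = "Pearson r vs block-face image") +
    ggplot2::theme_minimal()
}

#' Plot a tile plan
#'
#' @param object a `tile_plan`.
#' @param ... unused.
#' @return A ggplot of tile footprints numbered in visit order.
#' @export
autoplot.tile_plan <- function(object, ...) {
  df <- object$tiles
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x_mm, xmax = .data$x_mm + object$fov_mm[1],
      ymin = .data$y_mm, ymax = .data$y_mm + object$fov_mm[2]),
      fill = NA, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$x_mm + object$fov_mm[1] / 2,
      y = .data$y_mm + object$fov_mm[2] / 2,
      label = .data$visit_order)) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot regional counts and densities along the section series
#'
#' Rostro-caudal profile: per-section cell count (solid) and areal
#' density (dashed, secondary-scaled) per region.
#'
#' @param object a `region_counts` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.region_counts <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$region_id > 0)
  df$region <- factor(df$region_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$section_index,
                                   colour = .data$region)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_cells)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_cells)) +
    ggplot2::labs(x = "section", y = "cells per section",
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' Plot a PSF profile summary
#'
#' @param object a `psf_profile`.
#' @param ... unused.
#' @return A ggplot of fitted FWHM per axis.
#' @export
autoplot.psf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$axis, y = .data$fwhm_um)) +
    ggplot2::geom_col(width = 0.6, fill = "grey40") +
    ggplot2::labs(x = NULL, y = "FWHM (µm)") +
    ggplot2::theme_minimal()
}
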