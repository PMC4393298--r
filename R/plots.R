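#' Plot one channel (or the channel maximum) of a cycle image
#'
#' @param image_set A `cycle_images` object.
#' @param channel One of `"A"`, `"C"`, `"G"`, `"T"` or `"max"`.
#' @return A ggplot raster of the tile.
#' @export
plot_tile <- function(image_set, channel = "max") {
  M <- if (identical(channel, "max")) {
    max_channel_image(image_set)
  } else {
    image_set$channels[[channel]]
  }
  df <- tibble(
    x = rep(seq_len(ncol(M)) - 1L, each = nrow(M)),
    y = rep(seq_len(nrow(M)) - 1L, times = ncol(M)),
    intensity = as.vector(M)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("cycle %d, channel %s",
                                  image_set$cycle, channel),
                  x = "x (px)", y = "y (px)", fill = "ADU")
}

#' Plot template positions
#'
#' @param object An `fc_template`.
#' @param truth Optional ground-truth cluster tibble overlaid for comparison.
#' @param ... Unused.
#' @return A ggplot of template positions (and true clusters, if given).
#' @export
autoplot.fc_template <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(shape = 3, colour = "steelblue", size = 1)
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(
      data = truth, ggplot2::aes(.data$x, .data$y),
      inherit.aes = FALSE, shape = 1, colour = "grey40", size = 1.6)
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("template: %d positions (golden %d, silver %d)",
                                  nrow(object$positions), object$golden_cycle,
                                  object$silver_cycle))
}

#' Plot an experiment-grid report
#'
#' Normalised intact-barcode percentage per grid cell, grouped by template
#' length and coloured by cluster density.
#'
#' @param object A `run_report` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.run_report <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(template = factor(.data$template_cycle_count),
           density = factor(.data$density_fraction))
  ggplot2::ggplot(df, ggplot2::aes(.data$template, .data$pct_barcoded_norm,
                                   fill = .data$density)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "template length (cycles)",
                  y = "% reads with intact barcode (normalised)",
                  fill = "density\n(fraction of optimal)")
}
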