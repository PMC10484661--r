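#' Plot a field image as an intensity raster
#'
#' @param image A [field_image].
#' @param records Optional detection tibble whose centroids are overlaid.
#' @return A ggplot.
#' @export
plot_field <- function(image, records = NULL) {
  assert_field_image(image)
  co <- pixel_coords(image)
  d <- tibble(x = as.vector(co$x), y = as.vector(co$y),
              intensity = as.vector(image$data))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "ADU") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(records) && nrow(records) > 0) {
    p <- p + ggplot2::geom_point(
      data = records,
      ggplot2::aes(.data$centroid_x_um, .data$centroid_y_um),
      inherit.aes = FALSE, shape = 1, colour = "red", size = 2)
  }
  p
}

#' @describeIn quant_droplets Field image with detected condensates overlaid.
#' @method autoplot droplet_quant
#' @export
autoplot.droplet_quant <- function(object, ...) {
  plot_field(object$image, object$records)
}

#' @describeIn quant_cells Field image with cells and foci overlaid.
#' @method autoplot cell_quant
#' @export
autoplot.cell_quant <- function(object, ...) {
  p <- plot_field(object$image, object$cells)
  if (nrow(object$foci) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$foci,
      ggplot2::aes(.data$centroid_x_um, .data$centroid_y_um),
      inherit.aes = FALSE, shape = 3, colour = "orange", size = 1.5)
  }
  p
}

#' Box-plot style summary figure for droplet records
#'
#' @param records Condensate record tibble (optionally with a `group`
#'   column for side-by-side comparison).
#' @param metric Column to plot.
#' @return A ggplot.
#' @export
plot_droplet_summary <- function(records, metric = "partition_ratio") {
  if (!metric %in% names(records)) abort(sprintf("No column `%s`.", metric))
  g <- if ("group" %in% names(records)) records$group else "all"
  d <- mutate(records, .group = g)
  ggplot2::ggplot(d, ggplot2::aes(.data$.group, .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
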