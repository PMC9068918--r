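#' Plot an image grid
#'
#' ggplot2 raster display of a phantom, view or prediction plane, with the
#' origin at the top-left as in sensor coordinates.
#'
#' @param x a matrix, `cell_image` or `sensor_view`.
#' @param title optional plot title.
#' @export
plot_view <- function(x, title = NULL) {
  m <- if (inherits(x, "cell_image")) x$intensity
       else if (inherits(x, "sensor_view")) x$image else x
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.numeric(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "a.u.")
}

#' Plot per-layer detector error rates
#'
#' @param layer_errors numeric vector of per-layer mean error rates (as from
#'   [detector_layer_errors()]), or a named list of several such vectors to
#'   compare models.
#' @export
plot_layer_errors <- function(layer_errors) {
  if (!is.list(layer_errors)) layer_errors <- list(model = layer_errors)
  df <- dplyr::bind_rows(lapply(names(layer_errors), function(nm)
    tibble::tibble(model = nm, layer = seq_along(layer_errors[[nm]]),
                   error_rate = layer_errors[[nm]])))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$layer), .data$error_rate,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "layer (1 = closest to sensor A)", y = "pixel error rate")
}
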