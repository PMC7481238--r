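# ggplot2 displays for the main result types

raster_to_tibble <- function(m, value_name = "value") {
  tibble(
    row = as.vector(row(m)), col = as.vector(col(m)),
    value = as.vector(m)
  ) |>
    dplyr::rename(!!value_name := "value")
}

#' Plot a transition map
#'
#' Five-class transition raster with a fixed colour key (greens for stable
#' noncropland, yellows for cropland, red/blue for conversion and
#' abandonment, purple for intermittent).
#'
#' @param object A [transition_map].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_map <- function(object, ...) {
  tc <- transition_classes()
  df <- raster_to_tibble(object$transition, "class") |>
    dplyr::mutate(class = factor(names(tc)[match(.data$class, tc)],
                                 levels = names(tc)))
  cols <- c(stable_noncrop = "#74a35c", stable_crop = "#e8d174",
            to_crop = "#c23b22", to_noncrop = "#3b6fc2",
            intermittent = "#8c5fa8")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, na.value = "grey85",
                               drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "transition") +
    ggplot2::theme_minimal()
}

#' Plot a yield surface or differential grid
#'
#' @param object A [yield_surface].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yield_surface <- function(object, ...) {
  df <- raster_to_tibble(object$values, "yield")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$yield)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey92") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0("yield (", object$crop, ")")) +
    ggplot2::theme_minimal()
}

#' Plot any numeric raster matrix
#'
#' @param m Numeric matrix.
#' @param name Legend title.
#' @return A ggplot object.
#' @export
plot_raster <- function(m, name = "value") {
  df <- raster_to_tibble(m, "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey92") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = name) +
    ggplot2::theme_minimal()
}
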