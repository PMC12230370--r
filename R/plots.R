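#' Heat-map of a per-cell layer
#'
#' Simple grid heat-map of any per-cell quantity (richness, mean DR, an
#' environmental layer, residuals) on the study grid.
#'
#' @param grid A `grid_spec`.
#' @param values Either a numeric vector aligned with `grid` rows or a tibble
#'   `(cell_id, value)`.
#' @param name Legend title.
#' @export
plot_cell_layer <- function(grid, values, name = "value") {
  stopifnot(inherits(grid, "grid_spec"))
  v <- if (is.data.frame(values)) {
    values$value[match(grid$cell_id, values$cell_id)]
  } else {
    values
  }
  df <- tibble::tibble(x = grid$x, y = grid$y, value = v)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}
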