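#' Build a planar equal-area grid
#'
#' Constructs the cell table of a regular `n_rows` x `n_cols` grid of square
#' cells, the spatial frame for all downstream assembly and modelling. Cells
#' are indexed row-major from 0; centroids sit at `((col + 0.5) * s,
#' (row + 0.5) * s)` km, so planar Euclidean distances between centroids are
#' exact. This emulates an equal-area projection by construction rather than
#' computing one.
#'
#' @param n_rows,n_cols Grid dimensions (counts, at least 1 each).
#' @param cell_size Cell edge length in km (default 100).
#' @param land_fraction Fraction of each cell covered by land, in `[0, 1]`;
#'   either a single value recycled to all cells or a vector in row-major cell
#'   order.
#'
#' @return A tibble of class `grid_spec` with columns `cell_id`, `row`, `col`
#'   (0-based), `x`, `y` (centroid km) and `land_fraction`, carrying the grid
#'   dimensions and cell size as attributes.
#' @export
#' @examples
#' g <- make_grid(3, 3, cell_size = 100)
#' grid_coords(g)
make_grid <- function(n_rows, n_cols, cell_size = 100, land_fraction = 1) {
  stopifnot(is_count(n_rows), is_count(n_cols), n_rows >= 1, n_cols >= 1)
  stopifnot(is.numeric(cell_size), cell_size > 0)
  n <- n_rows * n_cols
  lf <- rep_len(land_fraction, n)
  if (any(lf < 0 | lf > 1)) {
    abort("`land_fraction` values must lie in [0, 1]")
  }
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  g <- tibble::tibble(
    cell_id = row * n_cols + col,
    row = row,
    col = col,
    x = (col + 0.5) * cell_size,
    y = (row + 0.5) * cell_size,
    land_fraction = lf
  )
  new_grid(g, n_rows, n_cols, cell_size)
}

new_grid <- function(tbl, n_rows, n_cols, cell_size) {
  attr(tbl, "n_rows") <- as.integer(n_rows)
  attr(tbl, "n_cols") <- as.integer(n_cols)
  attr(tbl, "cell_size") <- cell_size
  class(tbl) <- unique(c("grid_spec", class(tbl)))
  tbl
}

grid_n_rows <- function(grid) attr(grid, "n_rows")
grid_n_cols <- function(grid) attr(grid, "n_cols")

#' @rdname make_grid
#' @param grid A `grid_spec`.
#' @export
grid_cell_size <- function(grid) attr(grid, "cell_size")

#' @rdname make_grid
#' @export
grid_coords <- function(grid) {
  as.matrix(grid[, c("x", "y")])
}

#' Drop cells with insufficient land coverage
#'
#' Retains cells whose land fraction is at least `min_land_fraction`
#' (default 0.25, i.e. cells with less than 25% land are removed); the
#' boundary value is kept. Cell ordering is preserved.
#'
#' @param grid A `grid_spec`.
#' @param min_land_fraction Minimum land fraction in `[0, 1]`.
#'
#' @return The filtered `grid_spec`.
#' @export
filter_land_cells <- function(grid, min_land_fraction = 0.25) {
  stopifnot(inherits(grid, "grid_spec"))
  stopifnot(min_land_fraction >= 0, min_land_fraction <= 1)
  keep <- grid$land_fraction >= min_land_fraction
  if (!any(keep)) {
    abort("no cells pass the land-coverage filter")
  }
  out <- dplyr::filter(grid, keep)
  new_grid(out, grid_n_rows(grid), grid_n_cols(grid), grid_cell_size(grid))
}

# place per-cell values of a (possibly filtered) grid into the full
# n_rows x n_cols matrix, NA elsewhere
cells_to_matrix <- function(grid, values) {
  stopifnot(length(values) == nrow(grid))
  m <- matrix(NA_real_, grid_n_rows(grid), grid_n_cols(grid))
  m[cbind(grid$row + 1L, grid$col + 1L)] <- values
  m
}

# rook-adjacency neighbour list over the retained cells of a grid, by row index
grid_rook_neighbours <- function(grid) {
  idx <- matrix(NA_integer_, grid_n_rows(grid), grid_n_cols(grid))
  idx[cbind(grid$row + 1L, grid$col + 1L)] <- seq_len(nrow(grid))
  nr <- nrow(idx)
  nc <- ncol(idx)
  lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$row[i] + 1L
    c <- grid$col[i] + 1L
    nb <- c(
      if (r > 1L) idx[r - 1L, c],
      if (r < nr) idx[r + 1L, c],
      if (c > 1L) idx[r, c - 1L],
      if (c < nc) idx[r, c + 1L]
    )
    nb[!is.na(nb)]
  })
}
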