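#' Simulate a spatially autocorrelated environmental field
#'
#' Generates one standardized value per retained grid cell by Gaussian-kernel
#' smoothing of white noise on the full grid: the smoothing bandwidth (in km)
#' controls the autocorrelation range, with `autocorr_range = 0` giving plain
#' white noise. Edge effects are removed by renormalizing with the smoothed
#' all-ones field. Values are standardized post hoc to mean 0 and (population)
#' standard deviation 1 over the retained cells.
#'
#' @param grid A `grid_spec` (possibly land-filtered).
#' @param autocorr_range Gaussian kernel standard deviation in km
#'   (`autocorr_range / cell_size` cells); non-negative.
#' @param seed Optional integer seed.
#' @param name Layer name recorded in the `"layer"` attribute.
#'
#' @return A tibble `(cell_id, value)`.
#' @export
simulate_env_field <- function(grid, autocorr_range = 0, seed = NULL,
                               name = "env") {
  stopifnot(inherits(grid, "grid_spec"), autocorr_range >= 0)
  sigma <- autocorr_range / grid_cell_size(grid)
  nr <- grid_n_rows(grid)
  nc <- grid_n_cols(grid)
  with_seed_(seed, {
    z <- matrix(rnorm(nr * nc), nr, nc)
    if (sigma > 0) {
      kr <- gauss_kernel_matrix(nr, sigma)
      kc <- gauss_kernel_matrix(nc, sigma)
      z <- (kr %*% z %*% kc) / (kr %*% matrix(1, nr, nc) %*% kc)
    }
    v <- z[cbind(grid$row + 1L, grid$col + 1L)]
    out <- tibble::tibble(cell_id = grid$cell_id, value = standardize(v))
    attr(out, "layer") <- name
    out
  })
}

gauss_kernel_matrix <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  exp(-d^2 / (2 * sigma^2))
}

#' Combine named layers into a wide cell table
#'
#' @param layers A named list of `(cell_id, value)` tibbles on one cell set.
#' @return A tibble with `cell_id` and one column per layer.
#' @export
bind_layers <- function(layers) {
  stopifnot(length(layers) > 0, !is.null(names(layers)))
  out <- tibble::tibble(cell_id = layers[[1]]$cell_id)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!identical(sort(l$cell_id), sort(out$cell_id))) {
      abort(paste0("layer `", nm, "` is not aligned with the others"))
    }
    out[[nm]] <- l$value[match(out$cell_id, l$cell_id)]
  }
  out
}
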