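#' Assemble a presence-absence matrix on a grid
#'
#' Turns per-species occupied-cell records into a cells x species
#' presence-absence matrix (PAM) restricted to the retained cells of `grid`.
#' Species whose entire range falls outside the retained cells are dropped
#' with a warning; a cell id that does not exist on the full grid at all is an
#' error naming the offending species.
#'
#' @param ranges A data frame with columns `species` and `cell_id` (one row
#'   per occupied cell; duplicates are collapsed).
#' @param grid A `grid_spec`, typically after [filter_land_cells()].
#'
#' @return A tibble of class `pam` with a `cell_id` column (one row per
#'   retained cell, in grid order) and one 0/1 integer column per species,
#'   species columns sorted by name.
#' @export
build_pam <- function(ranges, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ranges <- tibble::as_tibble(ranges)
  stopifnot(all(c("species", "cell_id") %in% names(ranges)))
  n_total <- grid_n_rows(grid) * grid_n_cols(grid)
  bad <- ranges$cell_id < 0 | ranges$cell_id >= n_total |
    ranges$cell_id != round(ranges$cell_id)
  if (any(bad)) {
    abort(paste0(
      "unknown cell ids for species: ",
      paste(unique(ranges$species[bad]), collapse = ", ")
    ))
  }
  kept <- dplyr::filter(ranges, .data$cell_id %in% grid$cell_id)
  lost <- setdiff(unique(ranges$species), unique(kept$species))
  if (length(lost) > 0) {
    warn(paste0(
      length(lost), " species dropped (range entirely outside retained ",
      "cells): ", paste(lost, collapse = ", ")
    ))
  }
  base <- tibble::tibble(cell_id = grid$cell_id)
  if (nrow(kept) == 0) {
    out <- base
  } else {
    wide <- kept |>
      dplyr::distinct(.data$species, .data$cell_id) |>
      dplyr::mutate(present = 1L) |>
      tidyr::pivot_wider(
        names_from = "species", values_from = "present", values_fill = 0L
      )
    wide <- wide[, c("cell_id", sort(setdiff(names(wide), "cell_id")))]
    out <- dplyr::left_join(base, wide, by = "cell_id")
    out[is.na(out)] <- 0L
  }
  class(out) <- unique(c("pam", class(out)))
  out
}

#' Species richness per cell
#'
#' Counts, for every retained cell, the species marked present in the PAM
#' (the PAM row sum).
#'
#' @param pam A `pam` as built by [build_pam()].
#'
#' @return A tibble with columns `cell_id` and `richness` (integer counts).
#' @export
richness <- function(pam) {
  stopifnot(inherits(pam, "pam"))
  m <- pam_matrix(pam)
  tibble::tibble(
    cell_id = pam$cell_id,
    richness = as.integer(rowSums(m))
  )
}

#' @rdname build_pam
#' @param pam A `pam`.
#' @export
pam_matrix <- function(pam) {
  stopifnot(inherits(pam, "pam"))
  sp <- setdiff(names(pam), "cell_id")
  m <- as.matrix(pam[, sp, drop = FALSE])
  if (length(sp) == 0) m <- matrix(0L, nrow(pam), 0)
  rownames(m) <- pam$cell_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname build_pam
#' @export
pam_species <- function(pam) {
  setdiff(names(pam), "cell_id")
}
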