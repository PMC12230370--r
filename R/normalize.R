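#' Normalize a cell table to z-scores
#'
#' Centres and scales every numeric covariate of a cell table to mean 0 and
#' standard deviation 1 over the retained cells, so coefficients of the
#' structural equations are standardized and comparable. Scaling uses the
#' population standard deviation (divide by n), a documented convention that
#' makes hand-computed checks exact. The raw `richness` count, when present,
#' is kept as is and a z-scored copy `richness_z` is added for modelling.
#'
#' The scaling constants are stored in the `"scaling"` attribute (a tibble
#' `variable`, `mean`, `sd`) so the transformation is invertible via
#' [denormalize_cells()].
#'
#' @param cell_table A data frame with a `cell_id` column and numeric
#'   covariates; at least 2 rows.
#' @param exclude Columns never scaled (default `cell_id` and `richness`).
#'
#' @return The normalized tibble with a `"scaling"` attribute.
#' @export
normalize_cells <- function(cell_table, exclude = c("cell_id", "richness")) {
  tbl <- tibble::as_tibble(cell_table)
  if (nrow(tbl) < 2) abort("need at least 2 cells to normalize")
  vars <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))], exclude)
  scaling <- purrr::map_dfr(vars, function(v) {
    x <- tbl[[v]]
    s <- pop_sd(x)
    if (s == 0) abort(paste0("variable `", v, "` has zero variance"))
    tibble::tibble(variable = v, mean = mean(x), sd = s)
  })
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    tbl[[v]] <- (tbl[[v]] - scaling$mean[i]) / scaling$sd[i]
  }
  if ("richness" %in% names(tbl) && !"richness_z" %in% names(tbl)) {
    s <- pop_sd(tbl$richness)
    if (s == 0) abort("variable `richness` has zero variance")
    tbl$richness_z <- (tbl$richness - mean(tbl$richness)) / s
    scaling <- dplyr::bind_rows(
      scaling,
      tibble::tibble(variable = "richness_z", mean = mean(tbl$richness), sd = s)
    )
  }
  attr(tbl, "scaling") <- scaling
  tbl
}

#' @rdname normalize_cells
#' @param scaling A scaling tibble as stored by [normalize_cells()]; defaults
#'   to the attribute on `cell_table`.
#' @export
denormalize_cells <- function(cell_table, scaling = attr(cell_table, "scaling")) {
  if (is.null(scaling)) abort("no scaling constants available")
  tbl <- tibble::as_tibble(cell_table)
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    if (v %in% names(tbl)) {
      tbl[[v]] <- tbl[[v]] * scaling$sd[i] + scaling$mean[i]
    }
  }
  attr(tbl, "scaling") <- NULL
  tbl
}
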