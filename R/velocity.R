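#' Climate-change velocity on a grid
#'
#' Computes, per retained cell, the mean over paleo snapshots of the
#' climate-change velocity: the temporal rate of change between the snapshot
#' and current conditions, `|current - paleo| / age` (units/yr), divided by the
#' local spatial gradient of the current layer (units/km), giving km/yr. Low
#' velocity marks long-term climatic stability.
#'
#' The spatial gradient is the Euclidean magnitude `sqrt(gx^2 + gy^2)` of the
#' central-difference gradient of the current layer; edge cells and cells next
#' to missing neighbours use one-sided differences, and a gradient component
#' with no usable neighbour contributes 0. Gradients are floored at
#' `gradient_floor` so flat terrain does not divide by zero; floored cells are
#' reported via a message.
#'
#' @param grid A `grid_spec` (possibly land-filtered).
#' @param current Tibble `(cell_id, value)` of current conditions on exactly
#'   the retained cells.
#' @param paleo Tibble `(cell_id, age, value)` of one or more snapshots; `age`
#'   is years before present (> 0) and each age must cover exactly the
#'   retained cells.
#' @param gradient_floor Minimum spatial gradient in units/km (default 1e-6).
#'
#' @return A tibble `(cell_id, value)`, `value` being the mean velocity in
#'   km/yr over snapshots.
#' @export
climate_velocity <- function(grid, current, paleo, gradient_floor = 1e-6) {
  stopifnot(inherits(grid, "grid_spec"))
  current <- tibble::as_tibble(current)
  paleo <- tibble::as_tibble(paleo)
  stopifnot(all(c("cell_id", "value") %in% names(current)))
  stopifnot(all(c("cell_id", "age", "value") %in% names(paleo)))
  if (!identical(sort(current$cell_id), sort(grid$cell_id))) {
    abort("`current` layer is not aligned with the grid's retained cells")
  }
  cur <- current$value[match(grid$cell_id, current$cell_id)]
  grad <- spatial_gradient(grid, cur)
  floored <- grad < gradient_floor
  if (any(floored)) {
    inform(paste0(
      sum(floored), " cell(s) with spatial gradient below the floor (",
      format(gradient_floor), " units/km); velocity there uses the floor"
    ))
    grad <- pmax(grad, gradient_floor)
  }
  ages <- sort(unique(paleo$age))
  if (any(ages <= 0)) abort("snapshot ages must be positive")
  vel <- vapply(ages, function(a) {
    snap <- dplyr::filter(paleo, .data$age == a)
    if (!identical(sort(snap$cell_id), sort(grid$cell_id))) {
      abort(paste0("paleo snapshot at age ", a, " is not aligned with the grid"))
    }
    old <- snap$value[match(grid$cell_id, snap$cell_id)]
    temporal <- abs(cur - old) / a
    temporal / grad
  }, numeric(nrow(grid)))
  vel <- matrix(vel, nrow = nrow(grid))
  tibble::tibble(cell_id = grid$cell_id, value = rowMeans(vel))
}

# Euclidean magnitude of the central-difference spatial gradient (units/km);
# one-sided at edges/missing neighbours, 0 where no neighbour is available
spatial_gradient <- function(grid, values) {
  m <- cells_to_matrix(grid, values)
  s <- grid_cell_size(grid)
  gx <- directional_diff(m, along = "col") / s
  gy <- directional_diff(m, along = "row") / s
  g <- sqrt(gx^2 + gy^2)
  g[cbind(grid$row + 1L, grid$col + 1L)]
}

directional_diff <- function(m, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") {
    return(t(directional_diff(t(m), "col")))
  }
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(NA_real_, nr, 1)
  left <- cbind(pad, m[, -nc, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], pad)
  central <- (right - left) / 2
  fwd <- right - m
  bwd <- m - left
  out <- central
  out[is.na(out)] <- fwd[is.na(out)]
  out[is.na(out)] <- bwd[is.na(out)]
  out[is.na(out) & !is.na(m)] <- 0
  out
}
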