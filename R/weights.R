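#' Spatial weight matrices on grid cells
#'
#' Builds a row-standardized spatial weights object over the retained cells of
#' a grid under one of three neighbour schemes: `queen` contiguity (the
#' default; 8-neighbour adjacency, also available as `rook` for 4-neighbour),
#' a `distance` band on centroid distances, or symmetrized `knn`
#' (k-nearest-neighbour union). The binary neighbour relation is symmetric
#' before standardization; rows with at least one neighbour sum to 1 and
#' isolated cells (allowed, but reported) keep zero rows.
#'
#' The eigenvalues of the row-standardized matrix, needed for the SAR
#' log-determinant, are computed once per object via the symmetric similarity
#' transform `D^{-1/2} B D^{-1/2}` and cached.
#'
#' @param grid A `grid_spec` of retained cells (at least 2).
#' @param scheme One of `"queen"`, `"rook"`, `"distance"`, `"knn"`.
#' @param radius Distance band radius in km (`scheme = "distance"`).
#' @param k Neighbour count (`scheme = "knn"`); must be `< n`.
#'
#' @return A list of class `spatial_weights`: `W` (dense row-standardized
#'   matrix), `B` (binary symmetric adjacency), `degrees`, `cell_id`, `n`,
#'   `scheme`.
#' @export
build_weights <- function(grid, scheme = c("queen", "rook", "distance", "knn"),
                          radius = NULL, k = NULL) {
  stopifnot(inherits(grid, "grid_spec"), nrow(grid) >= 2)
  scheme <- match.arg(scheme)
  n <- nrow(grid)
  B <- switch(scheme,
    queen = {
      dr <- abs(outer(grid$row, grid$row, "-"))
      dc <- abs(outer(grid$col, grid$col, "-"))
      (dr <= 1 & dc <= 1 & (dr + dc) > 0) * 1
    },
    rook = {
      dr <- abs(outer(grid$row, grid$row, "-"))
      dc <- abs(outer(grid$col, grid$col, "-"))
      ((dr + dc) == 1) * 1
    },
    distance = {
      stopifnot(!is.null(radius), radius > 0)
      D <- as.matrix(dist(grid_coords(grid)))
      (D <= radius & D > 0) * 1
    },
    knn = {
      stopifnot(!is.null(k), k >= 1)
      if (k >= n) abort("`k` must be smaller than the number of cells")
      D <- as.matrix(dist(grid_coords(grid)))
      diag(D) <- Inf
      Bk <- matrix(0, n, n)
      for (i in seq_len(n)) {
        Bk[i, order(D[i, ])[seq_len(k)]] <- 1
      }
      pmax(Bk, t(Bk)) # symmetrize by union
    }
  )
  dimnames(B) <- NULL
  degrees <- rowSums(B)
  if (any(degrees == 0)) {
    inform(paste0(sum(degrees == 0), " isolated cell(s) in the weights"))
  }
  W <- B / pmax(degrees, 1)
  structure(
    list(
      W = W, B = B, degrees = degrees, cell_id = grid$cell_id,
      n = n, scheme = scheme, cache = new.env(parent = emptyenv())
    ),
    class = "spatial_weights"
  )
}

#' @rdname build_weights
#' @param weights A `spatial_weights` object.
#' @export
as_weights_matrix <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  weights$W
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(
    "<spatial_weights> ", x$n, " cells, scheme = ", x$scheme,
    ", mean degree = ", format(mean(x$degrees), digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

# real eigenvalues of the row-standardized W (similar to a symmetric matrix
# because B is symmetric), cached on the object
weights_eigenvalues <- function(weights) {
  cache <- weights$cache
  if (is.null(cache$eigenvalues)) {
    d <- weights$degrees
    nz <- d > 0
    ev <- numeric(weights$n)
    if (any(nz)) {
      s <- 1 / sqrt(d[nz])
      M <- weights$B[nz, nz, drop = FALSE] * outer(s, s)
      ev[seq_len(sum(nz))] <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    }
    cache$eigenvalues <- sort(ev)
  }
  cache$eigenvalues
}

#' Admissible interval and log-Jacobian of the SAR transform
#'
#' `lambda_interval()` returns the open interval of spatial parameters for
#' which `I - lambda W` stays positive-definite, `(1/omega_min + delta,
#' 1/omega_max - delta)` with `omega` the eigenvalue bounds of `W` (the upper
#' bound is 1 for row-standardized weights). `log_jacobian()` is
#' `sum(log|1 - lambda omega_i|)`, the log-determinant term of the SAR
#' likelihood, computed from the cached eigenvalues.
#'
#' @param weights A `spatial_weights`.
#' @param delta Interval shrink (default 1e-5).
#' @param lambda Spatial parameter.
#' @export
lambda_interval <- function(weights, delta = 1e-5) {
  ev <- weights_eigenvalues(weights)
  lo <- if (min(ev) < 0) 1 / min(ev) else -Inf
  hi <- if (max(ev) > 0) 1 / max(ev) else Inf
  c(lo + delta, hi - delta)
}

#' @rdname lambda_interval
#' @export
log_jacobian <- function(weights, lambda) {
  ev <- weights_eigenvalues(weights)
  sum(log(abs(1 - lambda * ev)))
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the centred values and `S0`
#' the total weight. Under spatial independence its expectation is
#' `-1/(n - 1)`.
#'
#' @param values Numeric vector aligned with the weights' cells.
#' @param weights A `spatial_weights`.
#' @return The Moran's I value (unitless).
#' @export
morans_i <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  stopifnot(length(values) == weights$n)
  z <- values - mean(values)
  if (sum(z^2) == 0) abort("values have zero variance")
  s0 <- sum(weights$W)
  (weights$n / s0) * as.numeric(z %*% weights$W %*% z) / sum(z^2)
}
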