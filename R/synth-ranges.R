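#' Simulate species ranges by niche-driven spreading dye
#'
#' Gives every species an environmental optimum evolved on the tree by
#' unit-rate Brownian motion (one optimum per layer), seeds its range at the
#' best-matching land cell, and grows it by repeatedly annexing the
#' best-matching free rook-neighbour until a drawn range size is reached.
#' Match quality is the negative squared environmental distance to the
#' optimum, optionally perturbed per cell by normal noise of sd `niche_sd`
#' (with `niche_sd = 0` growth is deterministic given the optima). Ranges are
#' rook-connected by construction and every species occupies at least one
#' cell.
#'
#' Because optima are Brownian, closely related species get similar optima and
#' therefore overlapping ranges, emulating phylogenetic niche conservatism in
#' real range atlases. Only relative optima matter for placement.
#'
#' @param tree A `phylo`; tip labels become the species names.
#' @param grid A `grid_spec` of retained (land) cells.
#' @param env_layers Wide tibble (`cell_id` + one column per layer) on the
#'   retained cells, as from [bind_layers()].
#' @param niche_sd Sd of the per-cell suitability noise (default 0).
#' @param range_size_dist Either `NULL` (log-normal sizes around 5% of the
#'   land cells), a numeric vector of per-species sizes, or a
#'   `function(n_species)` returning sizes. Sizes above the number of land
#'   cells are truncated with a warning.
#' @param seed Optional integer seed.
#'
#' @return A `pam` (see [build_pam()]) with attributes `range_sizes` (the
#'   drawn, truncated sizes) and `optima` (species x layer matrix).
#' @export
simulate_ranges <- function(tree, grid, env_layers, niche_sd = 0,
                            range_size_dist = NULL, seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  check_metric_tree(tree)
  env_layers <- tibble::as_tibble(env_layers)
  stopifnot(identical(sort(env_layers$cell_id), sort(grid$cell_id)))
  env <- as.matrix(
    env_layers[match(grid$cell_id, env_layers$cell_id),
      setdiff(names(env_layers), "cell_id"),
      drop = FALSE
    ]
  )
  n_cells <- nrow(grid)
  species <- tree$tip.label
  n_sp <- length(species)
  nb <- grid_rook_neighbours(grid)
  with_seed_(seed, {
    optima <- vapply(
      seq_len(ncol(env)),
      function(j) ape::rTraitCont(tree, sigma = 1),
      numeric(n_sp)
    )
    rownames(optima) <- species
    sizes <- draw_range_sizes(range_size_dist, n_sp, n_cells)
    if (any(sizes > n_cells)) {
      warn(paste0(
        sum(sizes > n_cells), " range size(s) larger than the ", n_cells,
        " land cells; truncated"
      ))
      sizes <- pmin(sizes, n_cells)
    }
    occ <- purrr::map(seq_len(n_sp), function(s) {
      suit <- -rowSums((env - matrix(optima[s, ],
        n_cells, ncol(env),
        byrow = TRUE
      ))^2)
      if (niche_sd > 0) suit <- suit + rnorm(n_cells, sd = niche_sd)
      spread_dye(suit, nb, sizes[s])
    })
    ranges <- tibble::tibble(
      species = rep(species, lengths(occ)),
      cell_id = grid$cell_id[unlist(occ)]
    )
    pam <- build_pam(ranges, grid)
    attr(pam, "range_sizes") <- setNames(lengths(occ), species)
    attr(pam, "optima") <- optima
    pam
  })
}

draw_range_sizes <- function(range_size_dist, n_sp, n_cells) {
  sizes <- if (is.null(range_size_dist)) {
    pmax(1, round(rlnorm(n_sp, meanlog = log(0.05 * n_cells), sdlog = 0.75)))
  } else if (is.function(range_size_dist)) {
    range_size_dist(n_sp)
  } else {
    rep_len(range_size_dist, n_sp)
  }
  stopifnot(all(sizes >= 1), all(sizes == round(sizes)))
  as.integer(sizes)
}

# grow a range greedily from the best cell, annexing the best free neighbour;
# stops early if the frontier empties (range confined to a component)
spread_dye <- function(suit, nb, size) {
  taken <- logical(length(suit))
  seed_cell <- which.max(suit)
  taken[seed_cell] <- TRUE
  range_cells <- seed_cell
  frontier <- setdiff(nb[[seed_cell]], range_cells)
  while (length(range_cells) < size && length(frontier) > 0) {
    nxt <- frontier[which.max(suit[frontier])]
    taken[nxt] <- TRUE
    range_cells <- c(range_cells, nxt)
    frontier <- unique(c(setdiff(frontier, nxt), nb[[nxt]][!taken[nb[[nxt]]]]))
  }
  range_cells
}
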