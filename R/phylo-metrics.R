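#' Equal-splits measure and the DR tip speciation rate
#'
#' `equal_splits()` computes, for each tip, the equal-splits sum
#' `ES = sum_j l_j * (1/2)^(j-1)` over the edges on the tip's root-to-tip
#' path, with `l_1` the pendant edge and `j` increasing toward the root: each
#' step rootward halves the weight, so recent branches dominate. `dr_metric()`
#' is its reciprocal, the DR tip speciation-rate statistic: species in clades
#' that branch frequently (short recent edges) get high DR.
#'
#' The halving rule is applied per node passed, which is the standard binary
#' rule; polytomies are treated like a single split.
#'
#' @param tree A rooted `phylo` with positive branch lengths (Myr).
#' @param tips Tip labels to compute; defaults to all tips.
#'
#' @return A tibble `(species, es)` for `equal_splits()`, `(species, dr)` for
#'   `dr_metric()` with `dr = 1/es` in 1/Myr.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:3,(B:2,(C:1,D:1):1):1);")
#' equal_splits(tr)
#' dr_metric(tr)
equal_splits <- function(tree, tips = tree$tip.label) {
  check_metric_tree(tree)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    abort(paste0("tips not in tree: ", paste(tips[is.na(idx)], collapse = ", ")))
  }
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  root <- ape::Ntip(tree) + 1L
  es <- vapply(idx, function(tip) {
    node <- tip
    w <- 1
    total <- 0
    while (node != root) {
      total <- total + len_of[node] * w
      w <- w / 2
      node <- parent_of[node]
    }
    total
  }, numeric(1))
  tibble::tibble(species = tips, es = es)
}

#' @rdname equal_splits
#' @export
dr_metric <- function(tree, tips = tree$tip.label) {
  es <- equal_splits(tree, tips)
  tibble::tibble(species = es$species, dr = 1 / es$es)
}

#' Tip ages on an ultrametric tree
#'
#' The tip age (evolutionary time) of a species is the length of its pendant
#' edge: the time since its most recent splitting event. Averaged over the
#' species present in a cell, it proxies how long a region has been
#' accumulating lineages. A possible birth-death correction for unsampled
#' speciation events is not applied; the uncorrected pendant age is returned.
#'
#' @param tree A rooted, ultrametric `phylo` (branch lengths in Myr). Trees
#'   that are non-ultrametric beyond `tol` (relative root-to-tip spread)
#'   trigger a warning, not an error, since imputed trees can carry tiny
#'   numerical slack.
#' @param tol Relative ultrametricity tolerance (default 1e-6).
#'
#' @return A tibble `(species, tip_age)` in Myr.
#' @export
tip_ages <- function(tree, tol = 1e-6) {
  check_metric_tree(tree)
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_len(ape::Ntip(tree))]
  spread <- (max(tip_depths) - min(tip_depths)) / max(tip_depths)
  if (spread > tol) {
    warn(paste0(
      "tree is not ultrametric (relative root-to-tip spread ",
      format(spread, digits = 3), "); pendant ages may be inconsistent"
    ))
  }
  pend <- tree$edge.length[match(seq_len(ape::Ntip(tree)), tree$edge[, 2])]
  tibble::tibble(species = tree$tip.label, tip_age = pend)
}

check_metric_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) {
    abort("tree has non-positive branch lengths; zero-length edges are rejected")
  }
  invisible(tree)
}

#' Average tip metrics across a set of trees
#'
#' Computes per-species DR and tip age on each tree of an imputation set and
#' averages them species-wise: the averaging happens at the species level,
#' before any cell-level aggregation. All trees must share the same tip set.
#'
#' @param trees A `multiPhylo` or list of `phylo` objects on one tip set.
#'
#' @return A tibble `(species, dr, tip_age, n_trees)`.
#' @export
species_metrics_over_trees <- function(trees) {
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1)
  ref <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), ref)) {
      abort("all trees must share the same tip set")
    }
  }
  per_tree <- purrr::map(trees, function(tr) {
    dplyr::inner_join(dr_metric(tr), tip_ages(tr), by = "species")
  })
  dplyr::bind_rows(per_tree) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      dr = mean(.data$dr),
      tip_age = mean(.data$tip_age),
      n_trees = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-cell means of species-level metrics
#'
#' Unweighted arithmetic mean of per-species DR and tip age over the species
#' present in each cell. Cells with no species get `NA` and are meant to be
#' excluded from modelling downstream.
#'
#' @param pam A `pam` from [build_pam()].
#' @param tip_metrics A tibble `(species, dr, tip_age)` covering every species
#'   in the PAM (a missing metric is an error).
#'
#' @return A tibble `(cell_id, mean_dr, mean_tip_age, n_species)`.
#' @export
cell_means <- function(pam, tip_metrics) {
  stopifnot(inherits(pam, "pam"))
  tip_metrics <- tibble::as_tibble(tip_metrics)
  sp <- pam_species(pam)
  missing <- setdiff(sp, tip_metrics$species)
  if (length(missing) > 0) {
    abort(paste0(
      "tip metrics missing for species: ", paste(missing, collapse = ", ")
    ))
  }
  m <- pam_matrix(pam)
  ord <- match(sp, tip_metrics$species)
  dr <- tip_metrics$dr[ord]
  age <- tip_metrics$tip_age[ord]
  n_sp <- rowSums(m)
  sum_or_na <- function(v) {
    s <- as.numeric(m %*% v)
    unname(ifelse(n_sp > 0, s / n_sp, NA_real_))
  }
  tibble::tibble(
    cell_id = pam$cell_id,
    mean_dr = if (length(sp) > 0) sum_or_na(dr) else NA_real_,
    mean_tip_age = if (length(sp) > 0) sum_or_na(age) else NA_real_,
    n_species = as.integer(unname(n_sp))
  )
}
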