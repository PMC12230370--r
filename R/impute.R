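#' Stochastic taxonomic imputation of missing species
#'
#' Grafts species that lack phylogenetic data into their assigned clade on a
#' time-calibrated tree, producing a set of fully sampled replicate trees.
#' This is a simplified stochastic-addition scheme: for each missing species
#' an attachment edge is drawn with probability proportional to edge length
#' among the edges of its clade's crown subtree plus the clade's stem edge,
#' the attachment time is uniform along that edge, and the new pendant edge is
#' extended to the present, so ultrametricity is preserved exactly. The full
#' birth-death-weighted attachment of TACT-style samplers is intentionally not
#' implemented; this operation is the single isolation point for that
#' simplification.
#'
#' Species are grafted in deterministic (sorted) order and previously grafted
#' members of a clade enlarge its crown for later draws. Replicates differ
#' only by their random draws; a fixed `seed` makes the whole set
#' reproducible bit-for-bit.
#'
#' @param tree A rooted ultrametric `phylo`.
#' @param taxonomy A data frame `(species, clade)` covering at least the
#'   missing species; species already in the tree are used to locate each
#'   clade's crown. A missing species whose clade has no tips in the tree is
#'   an error listing the orphans.
#' @param n_replicates Number of imputed trees (default 100).
#' @param seed Optional integer seed.
#'
#' @return A `multiPhylo` of `n_replicates` trees, each containing all
#'   species. With no missing species the input tree is replicated unchanged.
#' @export
impute_missing_taxa <- function(tree, taxonomy, n_replicates = 100, seed = NULL) {
  check_metric_tree(tree)
  stopifnot(is_count(n_replicates), n_replicates >= 1)
  taxonomy <- tibble::as_tibble(taxonomy)
  stopifnot(all(c("species", "clade") %in% names(taxonomy)))
  missing <- sort(setdiff(taxonomy$species, tree$tip.label))
  if (length(missing) == 0) {
    out <- rep(list(tree), n_replicates)
    class(out) <- "multiPhylo"
    return(out)
  }
  clade_of <- setNames(taxonomy$clade, taxonomy$species)
  in_tree <- taxonomy$species[taxonomy$species %in% tree$tip.label]
  clade_tips <- split(in_tree, clade_of[in_tree])
  orphans <- missing[!clade_of[missing] %in% names(clade_tips)]
  if (length(orphans) > 0) {
    abort(paste0(
      "clade absent from tree for species: ", paste(orphans, collapse = ", ")
    ))
  }
  out <- with_seed_(seed, {
    lapply(seq_len(n_replicates), function(r) {
      tr <- tree
      for (sp in missing) {
        tr <- graft_into_clade(tr, sp, clade_of)
      }
      tr
    })
  })
  class(out) <- "multiPhylo"
  out
}

# graft one species onto an edge of its clade's crown subtree (plus stem),
# chosen proportionally to edge length, at a uniform height along the edge
graft_into_clade <- function(tree, species, clade_of) {
  clade <- clade_of[[species]]
  members <- intersect(names(clade_of)[clade_of == clade], tree$tip.label)
  tip_idx <- match(members, tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  present <- max(depths[seq_len(ape::Ntip(tree))])
  ages <- present - depths
  root <- ape::Ntip(tree) + 1L
  if (length(tip_idx) == 1) {
    # monotypic host: crown and stem coincide with the pendant edge
    candidates <- match(tip_idx, tree$edge[, 2])
  } else {
    mrca <- ape::getMRCA(tree, tip_idx)
    nodes <- subtree_nodes(tree, mrca)
    candidates <- which(tree$edge[, 1] %in% nodes)
    if (mrca != root) {
      candidates <- c(candidates, match(mrca, tree$edge[, 2]))
    }
  }
  lens <- tree$edge.length[candidates]
  e <- candidates[sample.int(length(candidates), 1, prob = lens)]
  child <- tree$edge[e, 2]
  age_child <- ages[child]
  t_attach <- age_child + runif(1) * tree$edge.length[e]
  phytools::bind.tip(
    tree, species,
    edge.length = t_attach,
    where = child,
    position = t_attach - age_child
  )
}

# all nodes (internal + tips) descending from `node`, inclusive
subtree_nodes <- function(tree, node) {
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  queue <- node
  while (length(queue) > 0) {
    cur <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, cur)
    queue <- c(queue, kids[[as.character(cur)]])
  }
  out
}
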