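# fixtures and independent oracles used across the suite

caterpillar_tree <- function() {
  ape::read.tree(text = "(A:3,(B:2,(C:1,D:1):1):1);")
}

balanced4_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# independent equal-splits oracle: walk the root-to-tip node path produced by
# ape::nodepath and accumulate halved weights from the tip side
es_path_oracle <- function(tree, tip) {
  root <- ape::Ntip(tree) + 1L
  path <- ape::nodepath(tree, root, which(tree$tip.label == tip))
  rows <- match(path[-1], tree$edge[, 2])
  lens <- rev(tree$edge.length[rows]) # pendant first
  sum(lens * 0.5^(seq_along(lens) - 1))
}

# brute-force Moran's I by explicit double loop
morans_i_oracle <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * z[i] * z[j]
      s0 <- s0 + W[i, j]
    }
  }
  (n / s0) * num / sum(z^2)
}

# independent forward birth-death run under the same documented stopping rule
# (stop at the n-th extant lineage, extend the present by u * Exp(n(b+d))),
# returning the crown age of the surviving tips
bd_crown_age_oracle <- function(b, d, n) {
  repeat {
    parent <- c(0L, 0L)
    t_birth <- c(0, 0)
    alive <- c(1L, 2L)
    t <- 0
    failed <- FALSE
    while (length(alive) != n) {
      if (length(alive) == 0) {
        failed <- TRUE
        break
      }
      t <- t + rexp(1, length(alive) * (b + d))
      i <- alive[sample.int(length(alive), 1)]
      if (runif(1) < b / (b + d)) {
        parent <- c(parent, i, i)
        t_birth <- c(t_birth, t, t)
        alive <- c(setdiff(alive, i), length(parent) - 1L, length(parent))
      } else {
        alive <- setdiff(alive, i)
      }
    }
    if (failed) next
    present <- t + runif(1) * rexp(1, n * (b + d))
    # MRCA of survivors: deepest common element of all root paths
    path_of <- function(i) {
      p <- i
      while (parent[i] != 0L) {
        i <- parent[i]
        p <- c(p, i)
      }
      p
    }
    common <- Reduce(intersect, lapply(alive, path_of))
    crown <- if (length(common) == 0) 0 else max(t_birth[common])
    return(present - crown)
  }
}

# exhaustive DFS oracle for summed path products from `from` to `to`
path_product_oracle <- function(edges, coefs, from, to) {
  total <- 0
  recurse <- function(node, prod) {
    if (node == to) {
      total <<- total + prod
      return(invisible())
    }
    out <- which(edges$from == node)
    for (e in out) {
      recurse(edges$to[e], prod * coefs[e])
    }
  }
  recurse(from, 1)
  total
}

# small random symmetric neighbour graph, row-standardized
random_weights <- function(n, p_edge = 0.15) {
  B <- matrix(rbinom(n * n, 1, p_edge), n, n)
  B <- pmax(B, t(B))
  diag(B) <- 0
  # ensure no isolated vertex so eigen bounds behave
  for (i in which(rowSums(B) == 0)) {
    j <- sample(setdiff(seq_len(n), i), 1)
    B[i, j] <- B[j, i] <- 1
  }
  d <- rowSums(B)
  W <- B / d
  cache <- new.env(parent = emptyenv())
  structure(
    list(
      W = W, B = B, degrees = d, cell_id = seq_len(n) - 1L, n = n,
      scheme = "random", cache = cache
    ),
    class = "spatial_weights"
  )
}
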