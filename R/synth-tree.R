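#' Simulate a birth-death tree conditioned on tip count
#'
#' Forward-simulates a constant-rate birth-death process from a crown of two
#' lineages and stops at the first moment the number of extant lineages
#' reaches `n_tips`; the present is then extended by a uniform fraction of an
#' exponential waiting time to the next event, so all pendant edges are
#' strictly positive. Extinct subtrees are pruned, leaving a rooted,
#' ultrametric tree with exactly `n_tips` extant tips. Histories that go
#' extinct before reaching `n_tips` are rejected and re-drawn, up to
#' `max_retries`.
#'
#' @param birth_rate Speciation rate (events/Myr), must exceed `death_rate`.
#' @param death_rate Extinction rate (events/Myr), non-negative.
#' @param n_tips Number of extant tips, at least 2.
#' @param seed Optional integer seed; a fixed seed reproduces the tree
#'   bit-identically.
#' @param max_retries Rejection cap (default 1000).
#'
#' @return A rooted ultrametric `phylo` with tips `t1 ... tn`.
#' @export
#' @examples
#' tr <- simulate_bd_tree(0.5, 0.1, 20, seed = 1)
#' ape::is.ultrametric(tr)
simulate_bd_tree <- function(birth_rate, death_rate, n_tips, seed = NULL,
                             max_retries = 1000) {
  stopifnot(birth_rate > death_rate, death_rate >= 0)
  stopifnot(is_count(n_tips), n_tips >= 2)
  with_seed_(seed, {
    for (i in seq_len(max_retries)) {
      tr <- bd_forward_once(birth_rate, death_rate, n_tips)
      if (!is.null(tr)) {
        return(tr)
      }
    }
    abort(paste0(
      "birth-death simulation went extinct in all ", max_retries, " attempts"
    ))
  })
}

# one forward pass; NULL on extinction before reaching n tips
bd_forward_once <- function(b, d, n) {
  cap <- 4L * n + 8L
  parent <- integer(cap)
  t_start <- numeric(cap)
  t_end <- numeric(cap)
  status <- character(cap) # "open", "split", "dead", "tip"
  parent[1:2] <- 0L
  t_start[1:2] <- 0
  status[1:2] <- "open"
  n_lin <- 2L
  alive <- c(1L, 2L)
  t <- 0
  while (length(alive) != n) {
    if (length(alive) == 0) {
      return(NULL)
    }
    rate <- length(alive) * (b + d)
    t <- t + rexp(1, rate)
    i <- alive[sample.int(length(alive), 1)]
    t_end[i] <- t
    if (runif(1) < b / (b + d)) {
      status[i] <- "split"
      if (n_lin + 2L > cap) {
        extra <- cap
        parent <- c(parent, integer(extra))
        t_start <- c(t_start, numeric(extra))
        t_end <- c(t_end, numeric(extra))
        status <- c(status, character(extra))
        cap <- cap + extra
      }
      kids <- n_lin + 1:2
      parent[kids] <- i
      t_start[kids] <- t
      status[kids] <- "open"
      n_lin <- n_lin + 2L
      alive <- c(setdiff(alive, i), kids)
    } else {
      status[i] <- "dead"
      alive <- setdiff(alive, i)
    }
  }
  present <- t + runif(1) * rexp(1, n * (b + d))
  t_end[alive] <- present
  status[alive] <- "tip"
  lineage_forest_to_phylo(
    parent[1:n_lin], t_start[1:n_lin], t_end[1:n_lin], status[1:n_lin]
  )
}

# prune extinct lineages, suppress unifurcations, emit a phylo via Newick
lineage_forest_to_phylo <- function(parent, t_start, t_end, status) {
  kids <- split(seq_along(parent), parent)
  n_tip <- 0L
  rec <- function(i) {
    len <- t_end[i] - t_start[i]
    if (status[i] == "tip") {
      n_tip <<- n_tip + 1L
      return(list(str = paste0("t", n_tip), len = len))
    }
    if (status[i] == "dead") {
      return(NULL)
    }
    parts <- purrr::compact(lapply(kids[[as.character(i)]], rec))
    if (length(parts) == 0) {
      return(NULL)
    }
    if (length(parts) == 1) {
      parts[[1]]$len <- parts[[1]]$len + len
      return(parts[[1]])
    }
    inner <- paste(
      vapply(parts, function(p) {
        paste0(p$str, ":", sprintf("%.17g", p$len))
      }, character(1)),
      collapse = ","
    )
    list(str = paste0("(", inner, ")"), len = len)
  }
  sides <- purrr::compact(lapply(c(1L, 2L), rec))
  txt <- if (length(sides) == 2) {
    paste0(
      "(", sides[[1]]$str, ":", sprintf("%.17g", sides[[1]]$len), ",",
      sides[[2]]$str, ":", sprintf("%.17g", sides[[2]]$len), ");"
    )
  } else {
    # one crown side died out entirely; its survivor subtree is the tree
    paste0(sides[[1]]$str, ";")
  }
  ape::read.tree(text = txt)
}
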