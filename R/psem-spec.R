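#' Define a piecewise SEM specification
#'
#' A pSEM spec is a directed acyclic graph over standardized variables: the
#' response (regional richness) and any other endogenous variables each get
#' one structural equation (their parents as predictors), all fitted as SAR
#' error models and scored jointly. The response must be a pure sink.
#'
#' @param edges A data frame with columns `from`, `to` (cause -> effect), or a
#'   character vector of `"from -> to"` strings.
#' @param response The response variable (default `"richness_z"`); must have
#'   no outgoing edges and at least one parent.
#' @param id Optional label used in ranking tables.
#'
#' @return A list of class `psem_spec`: `edges`, `vars`, `response`,
#'   `endogenous` (variables with parents), `exogenous`, `id`.
#' @export
#' @examples
#' psem_spec(c("aet -> richness_z", "temp_seasonality -> mean_dr",
#'             "mean_dr -> richness_z"))
psem_spec <- function(edges, response = "richness_z", id = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "\\s*->\\s*")
    stopifnot(all(lengths(parts) == 2))
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, character(1), 1),
      to = vapply(parts, `[[`, character(1), 2)
    )
  }
  edges <- tibble::as_tibble(edges)[, c("from", "to")]
  edges <- dplyr::distinct(edges)
  if (nrow(edges) == 0) abort("a psem_spec needs at least one edge")
  vars <- unique(c(edges$from, edges$to))
  if (!response %in% edges$to) {
    abort(paste0("response `", response, "` has no parents"))
  }
  if (response %in% edges$from) {
    abort(paste0("response `", response, "` must have no outgoing edges"))
  }
  order <- topological_order(edges, vars)
  if (is.null(order)) abort("specification contains a cycle")
  endogenous <- unique(edges$to)
  structure(
    list(
      edges = edges, vars = order, response = response,
      endogenous = endogenous, exogenous = setdiff(vars, endogenous),
      id = id %||% spec_signature(edges)
    ),
    class = "psem_spec"
  )
}

# Kahn's algorithm; NULL if cyclic; stable order (input var order among ties)
topological_order <- function(edges, vars) {
  indeg <- setNames(
    vapply(vars, function(v) sum(edges$to == v), integer(1)), vars
  )
  order <- character(0)
  avail <- vars[indeg == 0]
  while (length(avail) > 0) {
    v <- avail[[1]]
    avail <- avail[-1]
    order <- c(order, v)
    for (u in edges$to[edges$from == v]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) avail <- c(avail, u)
    }
  }
  if (length(order) != length(vars)) NULL else order
}

spec_signature <- function(edges) {
  paste(sort(paste(edges$from, edges$to, sep = "->")), collapse = ";")
}

parents_of <- function(spec, v) {
  spec$edges$from[spec$edges$to == v]
}

# is `anc` an ancestor of `v` (directed path)?
is_ancestor <- function(spec, anc, v) {
  frontier <- v
  seen <- character(0)
  while (length(frontier) > 0) {
    pa <- unique(unlist(lapply(frontier, parents_of, spec = spec)))
    pa <- setdiff(pa, seen)
    if (anc %in% pa) {
      return(TRUE)
    }
    seen <- c(seen, pa)
    frontier <- pa
  }
  FALSE
}

#' @export
print.psem_spec <- function(x, ...) {
  cat("<psem_spec> ", nrow(x$edges), " edges, response = ", x$response,
    "\n",
    sep = ""
  )
  for (v in intersect(rev(x$vars), x$endogenous)) {
    cat("  ", v, " ~ ", paste(parents_of(x, v), collapse = " + "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Enumerate candidate pSEM specifications
#'
#' Default generator for the candidate set: for each endogenous configuration
#' (e.g. speciation rate alone, evolutionary time alone, or both), every
#' exogenous variable takes a non-empty subset of roles among "directly
#' affects the response" and "affects each endogenous variable"; endogenous
#' variables always point at the response. The cross-product over exogenous
#' variables is deduplicated (the saturated spec appears exactly once) and
#' each spec is acyclicity-checked by construction. Explicit model lists can
#' be supplied instead via [psem_spec()].
#'
#' @param exogenous Character vector of exogenous variables (non-empty).
#' @param endogenous_configs List of character vectors: the endogenous
#'   configurations to cross (use `list(character(0))` for models with no
#'   mediator).
#' @param response Response variable name.
#' @param require_mediated If `TRUE`, drop candidates in which a config
#'   member ends up with no parents (no structural equation of its own).
#'   Summed-AICc ranking is only meaningful across models with the same set
#'   of equations, so candidate sets meant for joint ranking should set this.
#'
#' @return A named list of `psem_spec` objects (`m001`, `m002`, ...).
#' @export
enumerate_candidates <- function(exogenous, endogenous_configs,
                                 response = "richness_z",
                                 require_mediated = FALSE) {
  if (length(exogenous) == 0 || length(endogenous_configs) == 0) {
    abort("empty rule set: need exogenous variables and endogenous configs")
  }
  specs <- list()
  seen <- character(0)
  for (config in endogenous_configs) {
    targets <- c(response, config)
    roles <- purrr::map(seq_len(length(targets)), ~ utils::combn(
      targets, .x,
      simplify = FALSE
    ))
    roles <- purrr::flatten(roles) # all non-empty subsets
    grids <- rep(list(seq_along(roles)), length(exogenous))
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(combos))) {
      edges <- dplyr::bind_rows(
        purrr::map2_dfr(
          exogenous, as.integer(combos[i, ]),
          function(v, ri) tibble::tibble(from = v, to = roles[[ri]])
        ),
        tibble::tibble(from = config, to = rep(response, length(config)))
      )
      sig <- spec_signature(edges)
      if (sig %in% seen) next
      # config members without drawn parents simply enter as exogenous
      sp <- tryCatch(psem_spec(edges, response = response), error = function(e) NULL)
      if (is.null(sp)) next
      if (require_mediated && !all(config %in% sp$edges$to)) next
      seen <- c(seen, sig)
      specs[[length(specs) + 1]] <- sp
    }
  }
  names(specs) <- sprintf("m%03d", seq_along(specs))
  for (i in seq_along(specs)) specs[[i]]$id <- names(specs)[i]
  specs
}
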