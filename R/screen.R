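#' Collinearity screen within structural pathways
#'
#' Computes spatially corrected (Dutilleul) correlations for every pair of
#' variables inside each declared pathway group and greedily eliminates
#' collinear variables: while any remaining pair in a group has `|r|` above
#' `threshold`, the member of the worst pair with the larger mean absolute
#' correlation to the other remaining group members is dropped. All pairwise
#' results are reported regardless of the decision.
#'
#' @param cell_table Data frame with the variables (on the retained cells).
#' @param pathway_groups Named list of character vectors: the variables that
#'   compete within each structural pathway.
#' @param coords Matrix of cell coordinates, as [grid_coords()].
#' @param threshold Absolute-correlation threshold (default 0.8).
#' @param n_classes Distance classes passed to [dutilleul_setup()].
#'
#' @return A list of class `collinearity_screen`: `pairs` (tibble with
#'   `group`, `var1`, `var2`, `r`, `m_hat`, `p_value`, `dropped_flag`),
#'   `kept`, `dropped`.
#' @export
collinearity_screen <- function(cell_table, pathway_groups, coords,
                                threshold = 0.8, n_classes = NULL) {
  stopifnot(is.list(pathway_groups), !is.null(names(pathway_groups)))
  tbl <- tibble::as_tibble(cell_table)
  setup <- dutilleul_setup(coords, n_classes)
  all_pairs <- list()
  kept <- list()
  dropped <- character(0)
  for (g in names(pathway_groups)) {
    vars <- pathway_groups[[g]]
    stopifnot(all(vars %in% names(tbl)))
    pairs <- if (length(vars) >= 2) {
      combos <- utils::combn(vars, 2)
      purrr::map_dfr(seq_len(ncol(combos)), function(i) {
        v1 <- combos[1, i]
        v2 <- combos[2, i]
        res <- dutilleul_test(
          tbl[[v1]], tbl[[v2]],
          setup = setup, threshold = threshold
        )
        tibble::tibble(
          group = g, var1 = v1, var2 = v2, r = res$r, m_hat = res$m_hat,
          p_value = res$p_value, dropped_flag = res$dropped
        )
      })
    } else {
      tibble::tibble(
        group = character(), var1 = character(), var2 = character(),
        r = numeric(), m_hat = numeric(), p_value = numeric(),
        dropped_flag = logical()
      )
    }
    all_pairs[[g]] <- pairs
    remaining <- vars
    repeat {
      live <- pairs[pairs$var1 %in% remaining & pairs$var2 %in% remaining, ]
      live <- live[abs(live$r) > threshold, ]
      if (nrow(live) == 0) break
      worst <- live[which.max(abs(live$r)), ]
      drop_var <- pick_drop(worst$var1, worst$var2, remaining, tbl)
      remaining <- setdiff(remaining, drop_var)
      dropped <- c(dropped, drop_var)
    }
    kept[[g]] <- remaining
  }
  structure(
    list(
      pairs = dplyr::bind_rows(all_pairs), kept = kept,
      dropped = unique(dropped), threshold = threshold
    ),
    class = "collinearity_screen"
  )
}

# of a collinear pair, drop the variable with the larger mean |r| to the
# remaining variables (plain Pearson; ties broken by name order)
pick_drop <- function(v1, v2, remaining, tbl) {
  others <- function(v) setdiff(remaining, v)
  score <- function(v) {
    o <- others(v)
    if (length(o) == 0) {
      return(0)
    }
    mean(abs(vapply(o, function(u) cor(tbl[[v]], tbl[[u]]), numeric(1))))
  }
  s1 <- score(v1)
  s2 <- score(v2)
  if (s1 > s2 || (s1 == s2 && v1 > v2)) v1 else v2
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(
    "<collinearity_screen> ", nrow(x$pairs), " pairs, threshold ",
    x$threshold, "\n",
    sep = ""
  )
  if (length(x$dropped) > 0) {
    cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  } else {
    cat("dropped: none\n")
  }
  invisible(x)
}
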