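#' Rank candidate pSEM fits by AICc
#'
#' Sorts fitted candidates by total AICc (sum over equations) ascending and
#' reports the difference to the best model. Ties (equal AICc) are broken by
#' fewer parameters, then by stable input order, and flagged.
#'
#' @param fits A non-empty list of [fit_psem()] results.
#'
#' @return A list of class `psem_ranking`: `table` (tibble `model`, `k`,
#'   `aicc`, `delta_aicc`, `n_equations`, `fisher_C`, `dsep_p`, `saturated`,
#'   `tie`), `best` (the winning `psem_fit`).
#' @export
rank_and_select <- function(fits) {
  stopifnot(length(fits) >= 1)
  ids <- names(fits) %||% vapply(fits, function(f) f$spec$id, character(1))
  if (is.null(names(fits))) names(fits) <- ids
  tab <- purrr::imap_dfr(fits, function(f, id) {
    tibble::tibble(
      model = id,
      k = f$k_total,
      aicc = f$aicc_total,
      n_equations = length(f$fits),
      fisher_C = if (is.null(f$dsep)) NA_real_ else f$dsep$C,
      dsep_p = if (is.null(f$dsep)) NA_real_ else f$dsep$p_value,
      saturated = if (is.null(f$dsep)) NA else f$dsep$saturated
    )
  })
  eq_sets <- unique(vapply(
    fits, function(f) paste(sort(names(f$fits)), collapse = "+"), character(1)
  ))
  if (length(eq_sets) > 1) {
    warn(paste0(
      "candidates model different endogenous sets (",
      paste(eq_sets, collapse = " | "),
      "); summed AICc is only comparable within a set"
    ))
  }
  ord <- order(tab$aicc, tab$k, seq_len(nrow(tab)))
  tab <- tab[ord, ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$tie <- duplicated(tab$aicc) | duplicated(tab$aicc, fromLast = TRUE)
  tab <- tab[, c(
    "model", "k", "aicc", "delta_aicc", "n_equations",
    "fisher_C", "dsep_p", "saturated", "tie"
  )]
  structure(
    list(table = tab, best = fits[[tab$model[1]]]),
    class = "psem_ranking"
  )
}

#' @export
print.psem_ranking <- function(x, ...) {
  cat("<psem_ranking> ", nrow(x$table), " models, best = ",
    x$table$model[1], "\n",
    sep = ""
  )
  print(x$table, n = 10)
  invisible(x)
}

#' @export
autoplot.psem_ranking <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = rev(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta_aicc, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 2, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = expression(Delta * "AICc"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Direct, indirect, and total standardized effects
#'
#' For every variable with a directed path to the response, the direct effect
#' is the standardized coefficient of its edge to the response (0 if absent),
#' the indirect effect is the sum over all directed paths of length at least
#' two of the product of path coefficients, and the total is their sum.
#' Computed exactly through the nilpotent coefficient-matrix series
#' `sum_k B^k = (I - B)^{-1} - I`.
#'
#' @param fit A [fit_psem()] result.
#'
#' @return A tibble `(variable, direct, indirect, total)` sorted by `|total|`
#'   descending.
#' @export
path_effects <- function(fit) {
  stopifnot(inherits(fit, "psem_fit"))
  spec <- fit$spec
  vars <- spec$vars
  nv <- length(vars)
  B <- matrix(0, nv, nv, dimnames = list(vars, vars))
  for (i in seq_len(nrow(fit$paths))) {
    B[fit$paths$from[i], fit$paths$to[i]] <- fit$paths$estimate[i]
  }
  total_mat <- solve(diag(nv) - B) - diag(nv)
  resp <- spec$response
  out <- purrr::map_dfr(setdiff(vars, resp), function(v) {
    tibble::tibble(
      variable = v,
      direct = B[v, resp],
      indirect = total_mat[v, resp] - B[v, resp],
      total = total_mat[v, resp]
    )
  })
  out <- out[out$total != 0 | out$direct != 0, ]
  out[order(-abs(out$total)), ]
}
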