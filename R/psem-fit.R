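#' Fit a piecewise SEM with SAR error components
#'
#' Fits one SAR error regression per endogenous variable of the spec (its
#' parents as predictors) on a pre-normalized cell table, so every path
#' coefficient is standardized. The model score is the sum of the component
#' AICc values (likelihood-based scoring, which stays defined for saturated
#' models); Fisher's C and the d-separation claims are computed alongside
#' when `dsep = TRUE` and reported as `"SATURATED"` when the basis set is
#' empty. A shared weights object is used for every equation.
#'
#' @param spec A [psem_spec()].
#' @param cell_table Normalized cell table containing every spec variable;
#'   rows must be complete cases for those variables.
#' @param weights A [build_weights()] object aligned with `cell_table`.
#' @param dsep Compute d-separation tests and Fisher's C (default TRUE).
#'
#' @return An object of class `psem_fit`: `spec`, `fits` (named list of
#'   [fit_sar_error()] results), `aicc_total`, `k_total`, `r2` (named,
#'   per equation), `paths` (tidy per-edge coefficients), `dsep`.
#' @export
fit_psem <- function(spec, cell_table, weights, dsep = TRUE) {
  stopifnot(inherits(spec, "psem_spec"))
  tbl <- tibble::as_tibble(cell_table)
  missing_vars <- setdiff(spec$vars, names(tbl))
  if (length(missing_vars) > 0) {
    abort(paste0(
      "variables absent from cell table: ",
      paste(missing_vars, collapse = ", ")
    ))
  }
  if (any(!complete.cases(tbl[, spec$vars]))) {
    abort("cell table has incomplete cases for the model variables; drop empty cells first")
  }
  fits <- purrr::map(
    setNames(spec$endogenous, spec$endogenous),
    function(v) {
      f <- stats::reformulate(parents_of(spec, v), response = v)
      fit_sar_error(tbl, f, weights)
    }
  )
  paths <- purrr::imap_dfr(fits, function(fit, v) {
    td <- tidy(fit)
    td <- td[td$term != "(Intercept)", ]
    tibble::tibble(
      from = td$term, to = v, estimate = td$estimate,
      std.error = td$std.error, p.value = td$p.value,
      significant = td$p.value < 0.05
    )
  })
  out <- structure(
    list(
      spec = spec,
      fits = fits,
      aicc_total = sum(vapply(fits, function(f) f$aicc, numeric(1))),
      k_total = sum(vapply(fits, function(f) f$k, numeric(1))),
      r2 = vapply(fits, function(f) f$r2, numeric(1)),
      lambda = vapply(fits, function(f) f$lambda, numeric(1)),
      paths = paths,
      n = nrow(tbl),
      dsep = NULL
    ),
    class = "psem_fit"
  )
  if (dsep) {
    out$dsep <- dsep_tests(spec, tbl, weights)
  }
  out
}

#' d-separation tests and Fisher's C
#'
#' Builds the basis set of independence claims implied by the missing edges
#' of the DAG (one claim per non-adjacent variable pair with at least one
#' endogenous member, conditioning on the union of both variables' parents;
#' the topologically later variable is regressed). Each claim is tested by
#' adding the earlier variable to the SAR regression of the later one and
#' taking its two-sided coefficient p-value. Fisher's C is `-2 sum(log p)`
#' with `df = 2k` against the chi-square upper tail. Saturated specs (empty
#' basis set) carry the marker `"SATURATED"`: C is undefined there, never 0.
#'
#' @inheritParams fit_psem
#'
#' @return A list of class `psem_dsep`: `claims` (tibble `u`, `v`,
#'   `conditioning`, `p_value`), `C`, `df`, `p_value`, `saturated`.
#' @export
dsep_tests <- function(spec, cell_table, weights) {
  stopifnot(inherits(spec, "psem_spec"))
  tbl <- tibble::as_tibble(cell_table)
  basis <- basis_set(spec)
  if (nrow(basis) == 0) {
    return(structure(
      list(
        claims = basis, C = NA_real_, df = 0L, p_value = NA_real_,
        saturated = TRUE, marker = "SATURATED"
      ),
      class = "psem_dsep"
    ))
  }
  p_values <- vapply(seq_len(nrow(basis)), function(i) {
    u <- basis$u[i]
    v <- basis$v[i]
    cond <- strsplit(basis$conditioning[i], ", ")[[1]]
    cond <- setdiff(cond[nzchar(cond)], c(u, v))
    f <- stats::reformulate(c(cond, u), response = v)
    fit <- fit_sar_error(tbl, f, weights)
    unname(fit$p_value[u])
  }, numeric(1))
  basis$p_value <- p_values
  fc <- fisher_c(p_values)
  structure(
    c(list(claims = basis), fc, list(saturated = FALSE, marker = NA_character_)),
    class = "psem_dsep"
  )
}

#' @rdname dsep_tests
#' @param p_values Vector of independence-claim p-values.
#' @export
fisher_c <- function(p_values) {
  if (any(p_values == 0)) {
    warn("zero p-value floored at 1e-300 in Fisher's C")
    p_values <- pmax(p_values, 1e-300)
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p_value = pchisq(C, df, lower.tail = FALSE))
}

# basis set: non-adjacent ordered pairs, at least one endogenous member,
# regressing the topologically later variable on the union of both parents
basis_set <- function(spec) {
  vars <- spec$vars # already topologically ordered
  out <- list()
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      u <- vars[i]
      v <- vars[j] # v is topologically later, so v is not an ancestor of u
      if (u %in% spec$exogenous && v %in% spec$exogenous) next
      adjacent <- any(
        (spec$edges$from == u & spec$edges$to == v) |
          (spec$edges$from == v & spec$edges$to == u)
      )
      if (adjacent) next
      cond <- sort(unique(c(parents_of(spec, u), parents_of(spec, v))))
      out[[length(out) + 1]] <- tibble::tibble(
        u = u, v = v, conditioning = paste(cond, collapse = ", ")
      )
    }
  }
  if (length(out) == 0) {
    tibble::tibble(
      u = character(), v = character(), conditioning = character()
    )
  } else {
    dplyr::bind_rows(out)
  }
}

#' @export
print.psem_dsep <- function(x, ...) {
  if (x$saturated) {
    cat("<psem_dsep> saturated model: Fisher's C ", x$marker, "\n", sep = "")
  } else {
    cat(
      "<psem_dsep> C = ", format(x$C, digits = 5), ", df = ", x$df,
      ", p = ", format(x$p_value, digits = 4), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
tidy.psem_fit <- function(x, ...) {
  x$paths
}

#' @export
glance.psem_fit <- function(x, ...) {
  tibble::tibble(
    AICc = x$aicc_total, k = x$k_total, nobs = x$n,
    n_equations = length(x$fits),
    fisher_C = if (is.null(x$dsep)) NA_real_ else x$dsep$C,
    dsep_df = if (is.null(x$dsep)) NA_integer_ else x$dsep$df,
    dsep_p = if (is.null(x$dsep)) NA_real_ else x$dsep$p_value,
    saturated = if (is.null(x$dsep)) NA else x$dsep$saturated
  )
}

#' @export
print.psem_fit <- function(x, ...) {
  cat("<psem_fit> ", x$spec$id, ": ", length(x$fits), " equation(s), AICc = ",
    format(x$aicc_total, digits = 6), "\n",
    sep = ""
  )
  for (v in names(x$fits)) {
    cat(
      "  ", v, ": R2 = ", format(x$r2[[v]], digits = 3),
      ", lambda = ", format(x$lambda[[v]], digits = 3), "\n",
      sep = ""
    )
  }
  if (!is.null(x$dsep)) print(x$dsep)
  invisible(x)
}

#' @export
autoplot.psem_fit <- function(object, ...) {
  eff <- path_effects(object)
  long <- tidyr::pivot_longer(
    eff, c("direct", "indirect", "total"),
    names_to = "component", values_to = "effect"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$effect,
    y = stats::reorder(.data$variable, abs(.data$effect)),
    fill = .data$component
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(
      x = "standardized effect on the response", y = NULL,
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
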