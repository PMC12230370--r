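#' Fit a simultaneous-autoregressive (SAR) error model
#'
#' Maximum-likelihood fit of `y = X b + u`, `u = lambda W u + e`,
#' `e ~ N(0, sigma^2 I)`: an ordinary regression whose residuals carry
#' simultaneous spatial dependence through the row-standardized weight matrix
#' `W`. For a candidate `lambda`, with `A = I - lambda W`, regressing `A y` on
#' `A X` gives the profiled `b(lambda)` and `sigma^2(lambda) = e'e/n`, and the
#' profile log-likelihood
#' `l(lambda) = -(n/2)(log(2 pi sigma^2) + 1) + sum(log|1 - lambda w_i|)`
#' (eigenvalues `w_i` of `W`, computed once per weights object) is maximized
#' by Brent search over the admissible interval. The optimization is
#' deterministic; an estimate within 1e-6 of the interval boundary is an
#' error with diagnostics. Weights with no neighbours at all reduce the model
#' exactly to OLS with `lambda = 0`.
#'
#' Coefficient standard errors come from the observed information of the
#' profile fit at the optimum, `sigma^2 [(AX)'(AX)]^{-1}` (asymptotically the
#' information for `b` is orthogonal to `(lambda, sigma^2)`); p-values are
#' two-sided normal. The parameter count `k` includes the intercept, each
#' slope, `lambda`, and `sigma^2`.
#'
#' @param data A data frame (rows aligned with the weights' cells; when a
#'   `cell_id` column is present it must match the weights' `cell_id`).
#' @param formula Model formula, e.g. `richness_z ~ aet + temp_seasonality`.
#' @param weights A [build_weights()] object with `n == nrow(data)`.
#'
#' @return An object of class `sar_fit`: coefficients, standard errors,
#'   p-values, `lambda`, `sigma2`, `loglik`, `k`, `aic`, `aicc`, Nagelkerke
#'   pseudo-R2 `r2` (against the intercept-plus-lambda null), fitted values
#'   and raw/spatially filtered residuals. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_sar_error <- function(data, formula, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  data <- as.data.frame(data)
  if ("cell_id" %in% names(data) &&
    !identical(data$cell_id, weights$cell_id)) {
    abort("`data` rows are not aligned with the weights' cells")
  }
  mf <- model.frame(formula, data, na.action = NULL)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(X)
  if (anyNA(y) || anyNA(X)) abort("missing values in model variables")
  if (n != weights$n) abort("weights and data have different cell counts")
  if (n <= p + 3) abort("too few cells for the number of predictors")
  core <- sar_profile_fit(y, X, weights)
  k <- p + 2L
  fit <- structure(
    list(
      formula = formula, response = as.character(formula[[2]]),
      coefficients = core$beta, std_error = core$se,
      statistic = core$beta / core$se,
      p_value = 2 * pnorm(-abs(core$beta / core$se)),
      lambda = core$lambda, sigma2 = core$sigma2, loglik = core$loglik,
      n = n, k = k, aic = -2 * core$loglik + 2 * k,
      fitted = core$fitted,
      residuals = tibble::tibble(
        cell_id = weights$cell_id, raw = core$resid_raw,
        filtered = core$resid_filtered
      ),
      null_loglik = NULL, weights = weights, y = y, X = X
    ),
    class = "sar_fit"
  )
  fit$aicc <- aicc_value(fit$aic, k, n)
  if (p > 1) {
    null_core <- sar_profile_fit(y, X[, 1, drop = FALSE], weights)
    fit$null_loglik <- null_core$loglik
  } else {
    fit$null_loglik <- core$loglik
  }
  fit$r2 <- nagelkerke_value(fit$loglik, fit$null_loglik, n)
  fit
}

# profile-likelihood machinery shared by fit and d-separation regressions
sar_profile_fit <- function(y, X, weights, boundary_tol = 1e-6) {
  n <- length(y)
  W <- weights$W
  ev <- weights_eigenvalues(weights)
  no_neighbours <- all(weights$degrees == 0)
  Wy <- as.numeric(W %*% y)
  WX <- W %*% X
  prof <- function(lambda) {
    yt <- y - lambda * Wy
    Xt <- X - lambda * WX
    qr_x <- qr(Xt)
    beta <- qr.coef(qr_x, yt)
    e <- yt - Xt %*% beta
    sigma2 <- sum(e^2) / n
    -(n / 2) * (log(2 * pi * sigma2) + 1) + sum(log(abs(1 - lambda * ev)))
  }
  if (no_neighbours) {
    lambda <- 0
  } else {
    iv <- lambda_interval(weights)
    opt <- optimize(prof, interval = iv, maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
    if (min(lambda - iv[1], iv[2] - lambda) < boundary_tol) {
      abort(paste0(
        "SAR estimate at the boundary of the admissible interval: lambda = ",
        format(lambda, digits = 8), ", interval (",
        format(iv[1], digits = 6), ", ", format(iv[2], digits = 6), ")"
      ))
    }
    # flat-likelihood guard: an interior optimum indistinguishable from 0
    if (abs(prof(lambda) - prof(0)) < 1e-12) lambda <- 0
  }
  yt <- y - lambda * Wy
  Xt <- X - lambda * WX
  qr_x <- qr(Xt)
  beta <- qr.coef(qr_x, yt)
  e <- as.numeric(yt - Xt %*% beta)
  sigma2 <- sum(e^2) / n
  loglik <- -(n / 2) * (log(2 * pi * sigma2) + 1) +
    sum(log(abs(1 - lambda * ev)))
  xtx_inv <- solve(crossprod(Xt))
  se <- sqrt(diag(sigma2 * xtx_inv))
  names(se) <- colnames(X)
  list(
    beta = setNames(as.numeric(beta), colnames(X)), se = se,
    lambda = lambda, sigma2 = sigma2, loglik = loglik,
    fitted = as.numeric(X %*% beta),
    resid_raw = as.numeric(y - X %*% beta),
    resid_filtered = e
  )
}

aicc_value <- function(aic, k, n) {
  if (n <= k + 1) abort("AICc undefined: n <= k + 1")
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`, with `AIC = -2 loglik + 2k`. The
#' default method takes a raw AIC value plus `k` and `n`; the `sar_fit` and
#' `psem_fit` methods use the fit's stored quantities.
#'
#' @param x A fit or an AIC value.
#' @param ... Method arguments (`k`, `n` for the default method).
#' @export
aicc <- function(x, ...) UseMethod("aicc")

#' @rdname aicc
#' @param k,n Parameter count and sample size.
#' @export
aicc.default <- function(x, k, n, ...) {
  stopifnot(k >= 1)
  aicc_value(x, k, n)
}

#' @rdname aicc
#' @export
aicc.sar_fit <- function(x, n = x$n, ...) {
  aicc_value(x$aic, x$k, n)
}

#' Nagelkerke pseudo-R2 of a SAR fit
#'
#' `r2 = 1 - exp((2/n) (l_null - l_model))` against the intercept-plus-lambda
#' null on the same data. A model likelihood below the null reports 0 with a
#' warning.
#'
#' @param fit A `sar_fit`.
#' @param null_fit Optional `sar_fit` of the null model; defaults to the null
#'   likelihood stored on `fit`.
#' @export
nagelkerke_r2 <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "sar_fit"))
  l0 <- if (is.null(null_fit)) fit$null_loglik else null_fit$loglik
  nagelkerke_value(fit$loglik, l0, fit$n)
}

nagelkerke_value <- function(l_model, l_null, n) {
  if (l_model < l_null - 1e-8) {
    warn("model log-likelihood below the null; pseudo-R2 reported as 0")
    return(0)
  }
  max(0, 1 - exp((2 / n) * (l_null - l_model)))
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("<sar_fit> ", deparse(x$formula), "\n", sep = "")
  cat(
    "lambda = ", format(x$lambda, digits = 4),
    ", loglik = ", format(x$loglik, digits = 6),
    ", AICc = ", format(x$aicc, digits = 6),
    ", R2 = ", format(x$r2, digits = 3), "\n",
    sep = ""
  )
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.sar_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_error),
    statistic = unname(x$statistic),
    p.value = unname(x$p_value)
  )
}

#' @export
glance.sar_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2, logLik = x$loglik,
    AIC = x$aic, AICc = x$aicc, r.squared = x$r2, k = x$k, nobs = x$n
  )
}

#' @export
autoplot.sar_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$term, abs(.data$estimate))
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(
      x = "standardized coefficient", y = NULL,
      title = paste0(
        object$response, " (SAR error, lambda = ",
        format(object$lambda, digits = 3), ")"
      )
    ) +
    ggplot2::theme_minimal()
}
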