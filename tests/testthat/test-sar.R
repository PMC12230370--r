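test_that("a SAR fit with no neighbours reduces exactly to OLS", {
  withr::with_seed(51, {
    g <- make_grid(6, 6, cell_size = 1)
    w0 <- suppressMessages(build_weights(g, "distance", radius = 0.1))
    d <- data.frame(x = rnorm(36), z = rnorm(36))
    d$y <- 1 + 0.8 * d$x - 0.5 * d$z + rnorm(36)
    fit <- fit_sar_error(d, y ~ x + z, w0)
    ols <- lm(y ~ x + z, d)
    expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
    expect_equal(fit$lambda, 0)
    expect_equal(fit$sigma2, sum(resid(ols)^2) / 36, tolerance = 1e-12)
  })
})

test_that("profile likelihood at the optimum dominates lambda = 0", {
  withr::with_seed(52, {
    g <- make_grid(10, 10, cell_size = 1)
    w <- build_weights(g, "queen")
    W <- as_weights_matrix(w)
    u <- solve(diag(100) - 0.5 * W, rnorm(100))
    d <- data.frame(x = rnorm(100))
    d$y <- 0.4 * d$x + u
    fit <- fit_sar_error(d, y ~ x, w)
    # refit constrained at lambda = 0 is plain OLS; compare likelihoods
    ols <- lm(y ~ x, d)
    s2 <- sum(resid(ols)^2) / 100
    ll0 <- -(100 / 2) * (log(2 * pi * s2) + 1)
    expect_gte(fit$loglik, ll0)
    expect_gt(fit$lambda, 0)
  })
})

test_that("spatial filtering moves residual Moran's I toward its null expectation", {
  g <- make_grid(12, 12, cell_size = 1)
  w <- build_weights(g, "queen")
  W <- as_weights_matrix(w)
  n <- nrow(g)
  Ainv <- solve(diag(n) - 0.6 * W)
  null_i <- -1 / (n - 1)
  res <- withr::with_seed(53, {
    vapply(1:50, function(i) {
      x <- rnorm(n)
      y <- 0.5 * x + as.numeric(Ainv %*% rnorm(n, sd = 0.5))
      d <- data.frame(x = x, y = y)
      fit <- fit_sar_error(d, y ~ x, w)
      c(
        raw = morans_i(resid(lm(y ~ x, d)), w),
        filtered = morans_i(fit$residuals$filtered, w)
      )
    }, numeric(2))
  })
  closer <- abs(res["filtered", ] - null_i) < abs(res["raw", ] - null_i)
  expect_gt(mean(closer), 0.9)
})

test_that("AICc follows its closed form and guards its preconditions", {
  expect_equal(aicc(100, k = 3, n = 30), 100 + 24 / 26)
  expect_equal(aicc(100, k = 3, n = 1e9), 100, tolerance = 1e-6)
  expect_error(aicc(100, k = 3, n = 4), "undefined")
  expect_error(aicc(100, k = 0, n = 30))
  withr::with_seed(54, {
    g <- make_grid(5, 5, cell_size = 1)
    w <- build_weights(g, "queen")
    d <- data.frame(x = rnorm(25))
    d$y <- 0.3 * d$x + rnorm(25)
    fit <- fit_sar_error(d, y ~ x, w)
    expect_equal(fit$aicc, aicc(fit))
    expect_gte(fit$aicc, fit$aic)
    expect_equal(fit$k, 4) # intercept + slope + lambda + sigma2
  })
})

test_that("Nagelkerke pseudo-R2 spans the null and strong-signal limits", {
  g <- make_grid(15, 15, cell_size = 1)
  w <- build_weights(g, "queen")
  withr::with_seed(55, {
    d <- data.frame(x = rnorm(225))
    d$y <- rnorm(225) # pure noise: R2 near 0
    f0 <- fit_sar_error(d, y ~ x, w)
    expect_lt(f0$r2, 0.1)
    expect_gte(f0$r2, 0)
  })
  # strong structural signal, lambda = 0.5: R2 > 0.8
  cfg <- sim_config(
    grid_rows = 15, grid_cols = 15, cell_size = 1,
    env_autocorr_range = c(aet = 2, temp_seasonality = 2),
    true_direct_effects = c(aet = 0.6, temp_seasonality = 0.5),
    true_endogenous_effects = list(),
    sar_lambda = 0.5, noise_sd = 0.05, seed = 56
  )
  sim <- simulate_structural_cell_table(config = cfg)
  fs <- fit_sar_error(sim$cell_table, richness_z ~ aet + temp_seasonality, sim$weights)
  expect_gt(fs$r2, 0.8)
  expect_equal(nagelkerke_r2(fs), fs$r2)
})

test_that("fits are invariant to permuting the cell order", {
  withr::with_seed(57, {
    g <- make_grid(8, 8, cell_size = 1)
    w <- build_weights(g, "queen")
    W <- as_weights_matrix(w)
    x <- rnorm(64)
    y <- 0.5 * x + as.numeric(solve(diag(64) - 0.4 * W, rnorm(64)))
    d <- data.frame(x = x, y = y)
    fit <- fit_sar_error(d, y ~ x, w)
    perm <- sample(64)
    gp <- macrosem:::new_grid(g[perm, ], 8, 8, 1)
    wp <- build_weights(gp, "queen")
    fitp <- fit_sar_error(d[perm, ], y ~ x, wp)
    expect_equal(fitp$coefficients, fit$coefficients, tolerance = 1e-6)
    expect_equal(fitp$lambda, fit$lambda, tolerance = 1e-6)
    expect_equal(fitp$loglik, fit$loglik, tolerance = 1e-6)
  })
})

test_that("tidy, glance, and autoplot expose the fit", {
  withr::with_seed(58, {
    g <- make_grid(6, 6, cell_size = 1)
    w <- build_weights(g, "queen")
    d <- data.frame(x = rnorm(36))
    d$y <- 0.5 * d$x + rnorm(36)
    fit <- fit_sar_error(d, y ~ x, w)
    td <- tidy(fit)
    expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
    gl <- glance(fit)
    expect_equal(gl$nobs, 36)
    expect_s3_class(autoplot(fit), "ggplot")
  })
})
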