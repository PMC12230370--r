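test_that("spec construction validates the DAG", {
  sp <- psem_spec(c(
    "aet -> richness_z", "temp -> mean_dr", "mean_dr -> richness_z"
  ))
  expect_setequal(sp$endogenous, c("mean_dr", "richness_z"))
  expect_setequal(sp$exogenous, c("aet", "temp"))
  expect_error(
    psem_spec(c("a -> b", "b -> a", "a -> richness_z")),
    "cycle"
  )
  expect_error(
    psem_spec("richness_z -> a", response = "richness_z"),
    "no parents|outgoing"
  )
})

test_that("candidate enumeration crosses roles and deduplicates", {
  expect_length(
    enumerate_candidates("x", list("mean_dr"), response = "y"), 3
  )
  expect_length(
    enumerate_candidates(c("a", "b"), list("mean_dr"), response = "y"), 9
  )
  expect_length(
    enumerate_candidates(c("a", "b"), list("mean_dr"),
      response = "y", require_mediated = TRUE
    ), 8
  )
  # saturated spec appears exactly once across duplicate configs
  specs <- enumerate_candidates("x", list("mean_dr", "mean_dr"), response = "y")
  sigs <- vapply(specs, function(s) macrosem:::spec_signature(s$edges), character(1))
  expect_false(any(duplicated(sigs)))
  expect_error(enumerate_candidates(character(0), list()), "empty rule set")
})

test_that("the d-separation basis set tracks the missing edges", {
  saturated <- psem_spec(c(
    "a -> richness_z", "a -> mean_dr", "mean_dr -> richness_z"
  ))
  expect_equal(nrow(macrosem:::basis_set(saturated)), 0)
  one_missing <- psem_spec(c(
    "a -> mean_dr", "mean_dr -> richness_z"
  ))
  bs <- macrosem:::basis_set(one_missing)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$u, "a")
  expect_equal(bs$v, "richness_z")
})

test_that("Fisher's C matches the closed form", {
  fc <- fisher_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * (log(0.5) + log(0.5)), tolerance = 1e-10)
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  expect_equal(fc$df, 4L)
  expect_equal(fc$p_value, 0.5966, tolerance = 1e-4)
  expect_warning(fc0 <- fisher_c(c(0.5, 0)), "floored")
  expect_true(is.finite(fc0$C))
})

test_that("saturated fits carry the SATURATED marker, never a zero C", {
  cfg <- sim_config(
    grid_rows = 10, grid_cols = 10, cell_size = 1,
    env_autocorr_range = c(aet = 2),
    true_direct_effects = c(aet = 0.36, mean_dr = 0.1),
    true_endogenous_effects = list(mean_dr = c(aet = 0.5)),
    sar_lambda = 0.3, seed = 61
  )
  sim <- simulate_structural_cell_table(config = cfg)
  sat <- psem_spec(c(
    "aet -> richness_z", "aet -> mean_dr", "mean_dr -> richness_z"
  ))
  fit <- fit_psem(sat, sim$cell_table, sim$weights)
  expect_true(fit$dsep$saturated)
  expect_identical(fit$dsep$marker, "SATURATED")
  expect_true(is.na(fit$dsep$C))
  expect_equal(glance(fit)$saturated, TRUE)
})

test_that("total AICc is additive over equations", {
  cfg <- sim_config(
    grid_rows = 10, grid_cols = 10, cell_size = 1,
    env_autocorr_range = c(aet = 2, temp = 2),
    true_direct_effects = c(aet = 0.36, mean_dr = 0.1),
    true_endogenous_effects = list(mean_dr = c(temp = 0.5)),
    sar_lambda = 0.3, seed = 62
  )
  sim <- simulate_structural_cell_table(config = cfg)
  full <- fit_psem(
    psem_spec(c(
      "aet -> richness_z", "temp -> mean_dr", "mean_dr -> richness_z"
    )),
    sim$cell_table, sim$weights,
    dsep = FALSE
  )
  expect_equal(
    full$aicc_total,
    sum(vapply(full$fits, function(f) f$aicc, numeric(1)))
  )
  # dropping the mean_dr equation removes exactly its AICc component
  reduced <- fit_psem(
    psem_spec(c("aet -> richness_z", "mean_dr -> richness_z")),
    sim$cell_table, sim$weights,
    dsep = FALSE
  )
  expect_equal(
    full$aicc_total - reduced$aicc_total,
    full$fits$mean_dr$aicc +
      (full$fits$richness_z$aicc - reduced$fits$richness_z$aicc)
  )
})

test_that("path effects follow the chain rule and a DFS oracle", {
  # hand-checkable chain plus direct edge
  edges <- tibble::tibble(
    from = c("x", "m", "x"),
    to = c("m", "y", "y")
  )
  coefs <- c(0.5, 0.4, 0.3)
  fit <- structure(
    list(
      spec = psem_spec(edges, response = "y"),
      paths = tibble::tibble(
        from = edges$from, to = edges$to, estimate = coefs
      )
    ),
    class = "psem_fit"
  )
  eff <- path_effects(fit)
  x_row <- eff[eff$variable == "x", ]
  expect_equal(x_row$direct, 0.3)
  expect_equal(x_row$indirect, 0.5 * 0.4)
  expect_equal(x_row$total, 0.3 + 0.2)
  m_row <- eff[eff$variable == "m", ]
  expect_equal(m_row$direct, 0.4)
  expect_equal(m_row$indirect, 0)
  # random DAGs against the exhaustive path-product oracle
  withr::with_seed(63, {
    for (rep in 1:100) {
      nv <- sample(3:6, 1)
      vars <- c(paste0("v", seq_len(nv - 1)), "y")
      edges <- NULL
      for (i in seq_len(nv - 1)) {
        for (j in (i + 1):nv) {
          if (runif(1) < 0.5) {
            edges <- rbind(edges, data.frame(from = vars[i], to = vars[j]))
          }
        }
      }
      if (is.null(edges) || !("y" %in% edges$to)) next
      edges <- edges[edges$from != "y", , drop = FALSE]
      coefs <- round(runif(nrow(edges), -1, 1), 2)
      sp <- tryCatch(psem_spec(edges, response = "y"), error = function(e) NULL)
      if (is.null(sp)) next
      fit <- structure(
        list(spec = sp, paths = tibble::tibble(
          from = edges$from, to = edges$to, estimate = coefs
        )),
        class = "psem_fit"
      )
      eff <- path_effects(fit)
      for (v in eff$variable) {
        expect_equal(
          eff$total[eff$variable == v],
          path_product_oracle(edges, coefs, v, "y"),
          tolerance = 1e-10
        )
      }
    }
  })
})

test_that("ranking orders by AICc with documented tie-breaks", {
  mk <- function(aicc, k, id) {
    structure(
      list(
        spec = structure(list(id = id), class = "psem_spec"),
        fits = list(richness_z = list()), aicc_total = aicc, k_total = k,
        dsep = NULL
      ),
      class = "psem_fit"
    )
  }
  rk <- rank_and_select(list(a = mk(12.5, 5, "a"), b = mk(10, 5, "b")))
  expect_equal(rk$table$model, c("b", "a"))
  expect_equal(rk$table$delta_aicc, c(0, 2.5))
  # equal AICc: smaller k wins and the tie is flagged
  rk2 <- rank_and_select(list(big = mk(10, 7, "big"), small = mk(10, 5, "small")))
  expect_equal(rk2$table$model[1], "small")
  expect_true(all(rk2$table$tie))
})

test_that("pSEM estimates are invariant to permuting cells", {
  cfg <- sim_config(
    grid_rows = 9, grid_cols = 9, cell_size = 1,
    env_autocorr_range = c(aet = 2, temp = 2),
    true_direct_effects = c(aet = 0.36, mean_dr = 0.1),
    true_endogenous_effects = list(mean_dr = c(temp = 0.5)),
    sar_lambda = 0.3, seed = 64
  )
  sim <- simulate_structural_cell_table(config = cfg)
  sp <- psem_spec(c(
    "aet -> richness_z", "temp -> mean_dr", "mean_dr -> richness_z"
  ))
  fit <- fit_psem(sp, sim$cell_table, sim$weights, dsep = FALSE)
  perm <- withr::with_seed(65, sample(81))
  g <- make_grid(9, 9, cell_size = 1)
  gp <- macrosem:::new_grid(g[perm, ], 9, 9, 1)
  wp <- build_weights(gp, "queen")
  fitp <- fit_psem(sp, sim$cell_table[perm, ], wp, dsep = FALSE)
  expect_equal(fitp$paths$estimate, fit$paths$estimate, tolerance = 1e-6)
})
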