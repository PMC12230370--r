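test_that("birth-death simulation yields rooted ultrametric trees of the requested size", {
  tr <- simulate_bd_tree(0.5, 0.1, 40, seed = 42)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.rooted(tr))
  expect_equal(ape::Ntip(tr), 40)
  expect_false(any(duplicated(tr$tip.label)))
  depths <- ape::node.depth.edgelength(tr)[1:40]
  expect_lt((max(depths) - min(depths)) / max(depths), 1e-9)
  # 2 tips: always a cherry with equal pendant edges
  ch <- simulate_bd_tree(1.0, 0.0, 2, seed = 7)
  expect_equal(ape::Ntip(ch), 2)
  expect_equal(ch$edge.length[1], ch$edge.length[2])
  expect_gt(ch$edge.length[1], 0)
})

test_that("birth-death simulation is bit-identical under a fixed seed", {
  t1 <- simulate_bd_tree(0.5, 0.1, 60, seed = 123)
  t2 <- simulate_bd_tree(0.5, 0.1, 60, seed = 123)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("mean crown age matches an independent forward-simulation oracle", {
  n_rep <- 400
  ages_pkg <- withr::with_seed(11, {
    vapply(seq_len(n_rep), function(i) {
      tr <- simulate_bd_tree(0.5, 0.1, 15)
      max(ape::node.depth.edgelength(tr))
    }, numeric(1))
  })
  ages_oracle <- withr::with_seed(12, {
    vapply(seq_len(2000), function(i) bd_crown_age_oracle(0.5, 0.1, 15), numeric(1))
  })
  expect_lt(
    abs(mean(ages_pkg) - mean(ages_oracle)) / mean(ages_oracle),
    0.15
  )
})

test_that("environmental fields are standardized and autocorrelation tracks the range", {
  g <- make_grid(30, 30, cell_size = 1)
  w <- build_weights(g, "queen")
  f0 <- simulate_env_field(g, 0, seed = 1)
  expect_lt(abs(mean(f0$value)), 1e-9)
  expect_lt(abs(sqrt(mean((f0$value - mean(f0$value))^2)) - 1), 1e-9)
  n <- nrow(g)
  expect_lt(abs(morans_i(f0$value, w) - (-1 / (n - 1))), 0.1)
  f3 <- simulate_env_field(g, 3, seed = 1)
  expect_gt(morans_i(f3$value, w), 0.3)
})

test_that("structural generator is deterministic and honours the null model", {
  cfg <- sim_config(
    grid_rows = 12, grid_cols = 12, cell_size = 1,
    env_autocorr_range = c(aet = 2, temp_seasonality = 2),
    true_direct_effects = c(aet = 0, temp_seasonality = 0),
    true_endogenous_effects = list(),
    sar_lambda = 0, noise_sd = 1, seed = 4
  )
  s1 <- simulate_structural_cell_table(config = cfg)
  s2 <- simulate_structural_cell_table(config = cfg)
  expect_identical(s1$cell_table, s2$cell_table)
  # null slopes sit within 2 SE of zero at roughly the nominal rate
  inside <- unlist(lapply(1:20, function(i) {
    cfg$seed <- 400 + i
    s <- simulate_structural_cell_table(config = cfg)
    fit <- fit_sar_error(
      s$cell_table, richness_z ~ aet + temp_seasonality, s$weights
    )
    slopes <- tidy(fit)[-1, ]
    abs(slopes$estimate) < 2 * slopes$std.error
  }))
  expect_gte(mean(inside), 0.8)
})

test_that("inadmissible spatial parameters are rejected", {
  cfg <- sim_config(grid_rows = 5, grid_cols = 5, cell_size = 1,
    env_autocorr_range = c(aet = 1),
    true_direct_effects = c(aet = 0.3),
    true_endogenous_effects = list(), sar_lambda = 0.2, seed = 1)
  cfg$sar_lambda <- -50 # outside the eigenvalue bounds of any queen grid
  expect_error(
    simulate_structural_cell_table(config = cfg),
    "admissible interval"
  )
})

test_that("spreading-dye ranges conserve sizes, connectivity, and track optima", {
  tree <- simulate_bd_tree(0.5, 0.1, 30, seed = 5)
  g <- make_grid(15, 15, cell_size = 1)
  env <- bind_layers(list(grad = {
    f <- simulate_env_field(g, 0, seed = 1)
    f$value <- as.numeric(scale(g$x)) # single monotone layer
    f
  }))
  pam <- simulate_ranges(tree, g, env, niche_sd = 0, seed = 3)
  sizes <- attr(pam, "range_sizes")
  m <- pam_matrix(pam)
  expect_equal(unname(colSums(m)[names(sizes)]), unname(sizes))
  expect_true(all(colSums(m) >= 1))
  # ranges are rook-connected
  nb <- macrosem:::grid_rook_neighbours(g)
  connected <- vapply(seq_len(ncol(m)), function(j) {
    cells <- which(m[, j] == 1)
    seen <- cells[1]
    repeat {
      grow <- unique(unlist(nb[seen]))
      grow <- intersect(grow, cells)
      if (all(grow %in% seen)) break
      seen <- union(seen, grow)
    }
    length(seen) == length(cells)
  }, logical(1))
  expect_true(all(connected))
  # niche tracking: optimum rank-correlates with range-centroid environment
  opt <- attr(pam, "optima")[colnames(m), 1]
  centroid_env <- vapply(seq_len(ncol(m)), function(j) {
    mean(env$grad[m[, j] == 1])
  }, numeric(1))
  expect_gt(cor(opt, centroid_env, method = "spearman"), 0.8)
  # size-1 ranges: richness equals the count of seed cells per cell
  pam1 <- simulate_ranges(tree, g, env,
    niche_sd = 0.5, range_size_dist = rep(1, 30), seed = 9
  )
  expect_equal(sum(richness(pam1)$richness), 30)
  # oversized ranges truncate with a warning
  expect_warning(
    simulate_ranges(tree, g, env, range_size_dist = rep(500, 30), seed = 2),
    "truncated"
  )
})
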