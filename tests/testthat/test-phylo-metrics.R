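test_that("equal splits and DR match hand computations on fixtures", {
  bal <- balanced4_tree()
  es <- equal_splits(bal)
  expect_equal(es$es, rep(1.5, 4), tolerance = 1e-12)
  expect_equal(dr_metric(bal)$dr, rep(2 / 3, 4), tolerance = 1e-12)
  cat <- caterpillar_tree()
  es_cat <- tibble::deframe(equal_splits(cat))
  expect_equal(es_cat[["D"]], 1.75, tolerance = 1e-12)
  expect_equal(es_cat[["A"]], 3, tolerance = 1e-12)
  dr_cat <- tibble::deframe(dr_metric(cat))
  expect_equal(dr_cat[["D"]], 4 / 7, tolerance = 1e-12)
  expect_equal(dr_cat[["A"]], 1 / 3, tolerance = 1e-12)
  # 2-tip tree: ES equals the pendant edge
  ch <- ape::read.tree(text = "(A:5,B:5);")
  expect_equal(equal_splits(ch)$es, c(5, 5))
})

test_that("DR agrees with an independent path-walk oracle on random trees", {
  withr::with_seed(21, {
    for (i in 1:100) {
      tr <- ape::rtree(sample(5:40, 1))
      dr <- tibble::deframe(dr_metric(tr))
      tip <- sample(tr$tip.label, 1)
      expect_equal(dr[[tip]], 1 / es_path_oracle(tr, tip), tolerance = 1e-12)
    }
  })
})

test_that("DR scales inversely with branch-length rescaling", {
  tr <- caterpillar_tree()
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 3.5
  expect_equal(equal_splits(tr2)$es, equal_splits(tr)$es * 3.5)
  expect_equal(dr_metric(tr2)$dr, dr_metric(tr)$dr / 3.5)
})

test_that("tip ages are pendant edge lengths and warn off-ultrametric", {
  ages <- tibble::deframe(tip_ages(caterpillar_tree()))
  expect_equal(ages[c("A", "B", "C", "D")], c(A = 3, B = 2, C = 1, D = 1))
  ch <- ape::read.tree(text = "(A:5,B:5);")
  expect_equal(tip_ages(ch)$tip_age, c(5, 5))
  skew <- ape::read.tree(text = "(A:5,B:3);")
  expect_warning(tip_ages(skew), "not ultrametric")
  expect_error(equal_splits(ape::read.tree(text = "(A:1,B:1,C:1);") |>
    ape::unroot()), "rooted")
})

test_that("imputation grafts inside the clade, preserves ultrametricity, is seeded", {
  tree <- simulate_bd_tree(0.5, 0.1, 25, seed = 8)
  tax <- synthetic_taxonomy(tree, n_clades = 5)
  extra <- tibble::tibble(
    species = paste0("new", 1:4),
    clade = rep(unique(tax$clade)[1:2], 2)
  )
  tax_all <- dplyr::bind_rows(tax, extra)
  trees <- impute_missing_taxa(tree, tax_all, n_replicates = 10, seed = 3)
  expect_length(trees, 10)
  for (tr in trees) {
    expect_equal(ape::Ntip(tr), 29)
    d <- ape::node.depth.edgelength(tr)[1:29]
    expect_lt((max(d) - min(d)) / max(d), 1e-6)
    expect_true(all(extra$species %in% tr$tip.label))
  }
  # grafted species land inside their clade (crown or stem): on a tree with
  # monophyletic clades, the enlarged clade stays exactly monophyletic
  fx <- ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);")
  fx_tax <- tibble::tibble(
    species = c("A", "B", "C", "D", "n1", "n2"),
    clade = c("ab", "ab", "cd", "cd", "ab", "cd")
  )
  for (s in 1:20) {
    tr_fx <- impute_missing_taxa(fx, fx_tax, 1, seed = s)[[1]]
    for (cl in c("ab", "cd")) {
      members <- fx_tax$species[fx_tax$clade == cl]
      sub <- ape::extract.clade(tr_fx, ape::getMRCA(tr_fx, members))
      expect_setequal(sub$tip.label, members)
    }
  }
  # monotypic host: the new tip attaches on the host's pendant edge
  mono_tax <- tibble::tibble(
    species = c("A", "B", "C", "D", "sister_of_A"),
    clade = c("solo", "b", "c", "d", "solo")
  )
  tr_solo <- impute_missing_taxa(fx, mono_tax, 1, seed = 4)[[1]]
  pair <- ape::extract.clade(
    tr_solo, ape::getMRCA(tr_solo, c("A", "sister_of_A"))
  )
  expect_setequal(pair$tip.label, c("A", "sister_of_A"))
  # no missing species: replicates are the input tree
  same <- impute_missing_taxa(tree, tax, n_replicates = 3)
  expect_identical(ape::write.tree(same[[1]]), ape::write.tree(tree))
  # orphan clade errors listing the species
  orphan <- dplyr::bind_rows(
    tax, tibble::tibble(species = "ghost", clade = "clade_nowhere")
  )
  expect_error(impute_missing_taxa(tree, orphan, 2, seed = 1), "ghost")
  # imputation onto a pendant edge shortens the host's tip age
  host <- tax$species[1]
  mono <- tibble::tibble(species = "sister_sp", clade = "solo")
  tax_mono <- dplyr::bind_rows(
    tibble::tibble(species = host, clade = "solo"),
    tax[-1, ], mono
  )
  tr_m <- impute_missing_taxa(tree, tax_mono, 1, seed = 2)[[1]]
  age_before <- tibble::deframe(tip_ages(tree))[[host]]
  age_after <- tibble::deframe(tip_ages(tr_m))[[host]]
  expect_lt(age_after, age_before)
})

test_that("species metrics average over trees and respect tip-set checks", {
  tr <- caterpillar_tree()
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  out <- species_metrics_over_trees(list(tr, tr2))
  one <- dplyr::inner_join(dr_metric(tr), tip_ages(tr), by = "species")
  expect_equal(
    out$dr[match(one$species, out$species)],
    (one$dr + one$dr / 2) / 2
  )
  expect_equal(out$n_trees, rep(2L, 4))
  # identical trees reproduce single-tree values
  same <- species_metrics_over_trees(list(tr, tr))
  expect_equal(same$dr[match(one$species, same$species)], one$dr)
  mism <- ape::read.tree(text = "(X:1,Y:1);")
  expect_error(species_metrics_over_trees(list(tr, mism)), "same tip set")
})

test_that("cell means are bounded, symmetric, and strict about coverage", {
  g <- make_grid(2, 2)
  pam <- build_pam(
    tibble::tibble(species = c("A", "B", "A"), cell_id = c(0L, 0L, 1L)), g
  )
  metrics <- tibble::tibble(
    species = c("A", "B"), dr = c(0.2, 0.4), tip_age = c(1, 3)
  )
  cm <- cell_means(pam, metrics)
  expect_equal(cm$mean_dr[1], 0.3)
  expect_equal(cm$mean_tip_age[1], 2)
  expect_equal(cm$mean_dr[2], 0.2)
  expect_true(all(is.na(cm$mean_dr[3:4])))
  expect_true(all(cm$mean_dr >= 0.2 & cm$mean_dr <= 0.4, na.rm = TRUE))
  # permutation of species order does not matter
  cm2 <- cell_means(pam, metrics[2:1, ])
  expect_equal(cm, cm2)
  expect_error(cell_means(pam, metrics[1, ]), "B")
})
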