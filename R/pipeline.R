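#' Default run configuration
#'
#' Returns the configuration list for a fully simulated demo run: a 20 x 20
#' grid of 100 km cells, 120 species, 20% of species held out of the tree and
#' re-imputed with 100 replicate trees, queen weights, a 0.8 screening
#' threshold, and the default candidate rules (productivity and temperature
#' seasonality as exogenous, the speciation rate as mediator). Every field can
#' be overridden via the YAML run file; exactly one of `simulation` or
#' `inputs` may be present.
#'
#' @param seed Master seed; every stage derives a substream from it.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulation = list(
      grid_rows = 20, grid_cols = 20, cell_size = 100,
      n_species = 120, birth_rate = 0.5, death_rate = 0.1,
      missing_fraction = 0.2, n_clades = 12,
      env_autocorr_range = list(
        temp_seasonality = 300, precip_seasonality = 300,
        topo_complexity = 200, aet = 300, climate_velocity = 300
      ),
      niche_sd = 0.1
    ),
    weights = list(scheme = "queen"),
    imputation = list(n_replicates = 100),
    screening = list(
      threshold = 0.8,
      pathways = list(
        environment = c(
          "temp_seasonality", "precip_seasonality", "topo_complexity",
          "aet", "climate_velocity"
        ),
        evolution = c("mean_dr", "mean_tip_age")
      )
    ),
    models = list(
      exogenous = c("aet", "temp_seasonality"),
      endogenous_configs = list("mean_dr"),
      response = "richness_z"
    )
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> assemble -> metrics -> screen -> fit -> report as
#' one reproducible run: simulates the tree, environmental fields and ranges
#' (or, with an `inputs` block, reads a Newick tree, a ranges CSV and a cell
#' covariate CSV), builds the PAM and richness, imputes held-out species over
#' replicate trees, aggregates DR and tip ages per cell, normalizes, screens
#' collinear predictors, enumerates and fits the candidate pSEMs with shared
#' SAR weights, and ranks them by AICc. All artifacts (CSV/YAML plus a
#' manifest with the seed and md5 checksums) are written under `out_dir`;
#' rerunning the same config reproduces identical checksums. Any stage
#' failure aborts with the stage name.
#'
#' @param config A configuration list (see [default_config()]) or the path to
#'   a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with the run artifacts: `grid`, `pam`,
#'   `cell_table`, `tip_metrics`, `screen`, `fits`, `ranking`, `effects`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  sim <- stage("simulate", {
    simulate_stage(config, seed)
  })
  asm <- stage("assemble", {
    pam <- build_pam(sim$ranges, sim$grid)
    rich <- richness(pam)
    list(pam = pam, richness = rich)
  })
  met <- stage("metrics", {
    trees <- impute_missing_taxa(
      sim$tree_observed, sim$taxonomy,
      n_replicates = config$imputation$n_replicates %||% 100,
      seed = substream(seed, "imputation")
    )
    tip_metrics <- species_metrics_over_trees(trees)
    cm <- cell_means(asm$pam, tip_metrics)
    list(trees = trees, tip_metrics = tip_metrics, cell_means = cm)
  })
  tab <- stage("cell_table", {
    tbl <- asm$richness |>
      dplyr::inner_join(met$cell_means, by = "cell_id") |>
      dplyr::inner_join(sim$env, by = "cell_id") |>
      dplyr::filter(.data$n_species > 0) |>
      dplyr::select(-"n_species")
    grid_kept <- sim$grid[match(tbl$cell_id, sim$grid$cell_id), ]
    grid_kept <- new_grid(
      grid_kept, grid_n_rows(sim$grid), grid_n_cols(sim$grid),
      grid_cell_size(sim$grid)
    )
    list(table = normalize_cells(tbl), grid = grid_kept)
  })
  scr <- stage("screen", {
    collinearity_screen(
      tab$table,
      pathway_groups = config$screening$pathways,
      coords = grid_coords(tab$grid),
      threshold = config$screening$threshold %||% 0.8
    )
  })
  mod <- stage("fit", {
    w <- build_weights(
      tab$grid,
      scheme = config$weights$scheme %||% "queen",
      radius = config$weights$radius,
      k = config$weights$k
    )
    exo <- intersect(config$models$exogenous, unlist(scr$kept))
    specs <- enumerate_candidates(
      exogenous = exo,
      endogenous_configs = config$models$endogenous_configs,
      response = config$models$response %||% "richness_z",
      require_mediated = TRUE
    )
    fits <- purrr::map(specs, fit_psem,
      cell_table = tab$table, weights = w
    )
    ranking <- rank_and_select(fits)
    list(
      weights = w, fits = fits, ranking = ranking,
      effects = path_effects(ranking$best)
    )
  })
  manifest <- stage("write", {
    write_run_outputs(
      out_dir, config, asm, met, tab, scr, mod
    )
  })
  invisible(list(
    grid = tab$grid, pam = asm$pam, cell_table = tab$table,
    tip_metrics = met$tip_metrics, screen = scr, fits = mod$fits,
    ranking = mod$ranking, effects = mod$effects, manifest = manifest
  ))
}

validate_config <- function(config) {
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    abort("config must contain exactly one of `simulation` or `inputs`")
  }
  invisible(config)
}

simulate_stage <- function(config, seed) {
  if (!is.null(config$inputs)) {
    return(read_inputs_stage(config))
  }
  s <- config$simulation
  grid <- make_grid(s$grid_rows, s$grid_cols, s$cell_size %||% 100)
  tree <- simulate_bd_tree(
    s$birth_rate, s$death_rate, s$n_species,
    seed = substream(seed, "tree")
  )
  ranges_env <- purrr::imap(s$env_autocorr_range, function(rng, nm) {
    simulate_env_field(grid, rng,
      seed = substream(seed, paste0("field_", nm)),
      name = nm
    )
  })
  env <- bind_layers(ranges_env)
  pam <- simulate_ranges(
    tree, grid, env,
    niche_sd = s$niche_sd %||% 0,
    seed = substream(seed, "ranges")
  )
  ranges <- tidyr::pivot_longer(
    tibble::as_tibble(pam), -"cell_id",
    names_to = "species", values_to = "present"
  ) |>
    dplyr::filter(.data$present == 1L) |>
    dplyr::select("species", "cell_id")
  taxonomy <- synthetic_taxonomy(tree, n_clades = s$n_clades %||% 10)
  n_missing <- round((s$missing_fraction %||% 0.2) * ape::Ntip(tree))
  # hold out species to re-impute, but keep every clade represented
  held_out <- with_seed_(substream(seed, "holdout"), {
    pool <- sample(tree$tip.label)
    left <- table(taxonomy$clade[match(tree$tip.label, taxonomy$species)])
    out <- character(0)
    for (sp in pool) {
      if (length(out) >= n_missing) break
      cl <- taxonomy$clade[taxonomy$species == sp]
      if (left[[cl]] > 1) {
        out <- c(out, sp)
        left[[cl]] <- left[[cl]] - 1L
      }
    }
    out
  })
  n_missing <- length(held_out)
  tree_observed <- if (n_missing > 0) {
    ape::drop.tip(tree, held_out)
  } else {
    tree
  }
  list(
    grid = grid, tree_full = tree, tree_observed = tree_observed,
    taxonomy = taxonomy, env = env, ranges = ranges
  )
}

read_inputs_stage <- function(config) {
  inp <- config$inputs
  tree <- ape::read.tree(inp$tree)
  ranges <- tibble::as_tibble(utils::read.csv(inp$ranges))
  env <- tibble::as_tibble(utils::read.csv(inp$env))
  g <- inp$grid
  grid <- make_grid(
    g$n_rows, g$n_cols, g$cell_size %||% 100,
    land_fraction = g$land_fraction %||% 1
  )
  grid <- filter_land_cells(grid, g$min_land_fraction %||% 0.25)
  taxonomy <- tibble::as_tibble(utils::read.csv(inp$taxonomy))
  list(
    grid = grid, tree_full = tree, tree_observed = tree,
    taxonomy = taxonomy, env = env, ranges = ranges
  )
}

#' Assign species to clades by tree structure
#'
#' Deterministic surrogate taxonomy for simulated data: tips are clustered
#' into `n_clades` groups by complete-linkage clustering of patristic
#' distances, so clades are monophyletic-ish groups a field taxonomy would
#' name.
#'
#' @param tree A `phylo`.
#' @param n_clades Number of clades.
#' @return A tibble `(species, clade)`.
#' @export
synthetic_taxonomy <- function(tree, n_clades = 10) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  cl <- stats::cutree(stats::hclust(d, method = "complete"), k = n_clades)
  tibble::tibble(
    species = names(cl),
    clade = paste0("clade_", cl)
  )
}

write_run_outputs <- function(out_dir, config, asm, met, tab, scr, mod) {
  fmt <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  paths <- c(
    pam = "pam.csv", cell_table = "cell_table.csv",
    tip_metrics = "tip_metrics.csv", screen = "screen_pairs.csv",
    model_table = "model_table.csv", effects = "effects.csv",
    scaling = "scaling.yaml", best_model = "best_model.yaml",
    config = "config.yaml"
  )
  fp <- function(nm) file.path(out_dir, paths[[nm]])
  utils::write.csv(fmt(asm$pam), fp("pam"), row.names = FALSE)
  utils::write.csv(fmt(tab$table), fp("cell_table"), row.names = FALSE)
  utils::write.csv(fmt(met$tip_metrics), fp("tip_metrics"), row.names = FALSE)
  utils::write.csv(fmt(scr$pairs), fp("screen"), row.names = FALSE)
  utils::write.csv(fmt(mod$ranking$table), fp("model_table"), row.names = FALSE)
  utils::write.csv(fmt(mod$effects), fp("effects"), row.names = FALSE)
  yaml::write_yaml(
    purrr::map(
      split(attr(tab$table, "scaling"), seq_len(nrow(attr(tab$table, "scaling")))),
      function(r) list(variable = r$variable, mean = signif(r$mean, 6), sd = signif(r$sd, 6))
    ),
    fp("scaling")
  )
  best <- mod$ranking$best
  yaml::write_yaml(
    list(
      model = best$spec$id,
      edges = paste(best$spec$edges$from, "->", best$spec$edges$to),
      aicc = signif(best$aicc_total, 6),
      r2 = as.list(signif(best$r2, 6)),
      lambda = as.list(signif(best$lambda, 6)),
      fisher_c = if (best$dsep$saturated) "SATURATED" else signif(best$dsep$C, 6),
      effects = purrr::pmap(
        mod$effects,
        function(variable, direct, indirect, total) {
          list(
            variable = variable, direct = signif(direct, 6),
            indirect = signif(indirect, 6), total = signif(total, 6)
          )
        }
      )
    ),
    fp("best_model")
  )
  yaml::write_yaml(config, fp("config"))
  files <- file.path(out_dir, unname(paths))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("macrosem")),
    files = as.list(setNames(
      unname(tools::md5sum(files)), basename(files)
    ))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}

#' Summarise a completed run
#'
#' Reads the artifacts of a [run_pipeline()] output directory and prints a
#' human-readable summary: the AICc ladder, the per-equation R2 of the best
#' model, its largest direct effects in order, and the residual Moran
#' diagnostics when present. Regeneration is idempotent.
#'
#' @param out_dir A completed run directory.
#' @return Invisibly, the report lines (character vector).
#' @export
pipeline_report <- function(out_dir) {
  need <- file.path(out_dir, c("model_table.csv", "effects.csv", "best_model.yaml"))
  if (!all(file.exists(need))) {
    abort(paste0("incomplete run directory: ", out_dir))
  }
  tab <- utils::read.csv(file.path(out_dir, "model_table.csv"))
  eff <- utils::read.csv(file.path(out_dir, "effects.csv"))
  best <- yaml::read_yaml(file.path(out_dir, "best_model.yaml"))
  lines <- c(
    paste0("models evaluated: ", nrow(tab)),
    if (nrow(tab) == 0) "no models evaluated" else c(
      paste0(
        "best model: ", best$model, " (AICc ", best$aicc,
        ", Fisher's C ", best$fisher_c, ")"
      ),
      paste0(
        "delta AICc to runner-up: ",
        if (nrow(tab) > 1) signif(tab$delta_aicc[2], 4) else NA
      ),
      paste0(
        "per-equation R2: ",
        paste(names(best$r2), signif(unlist(best$r2), 3),
          sep = " = ", collapse = ", "
        )
      ),
      "largest absolute direct effects:",
      {
        ord <- order(-abs(eff$direct))
        top <- head(eff[ord, ], 3)
        paste0(
          "  ", top$variable, ": ", signif(top$direct, 3)
        )
      }
    )
  )
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
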