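#' Scenario configuration
#'
#' Assembles (and optionally reads from a YAML file) the configuration of a
#' full three-epoch analysis: synthetic-landscape parameters, the number of
#' source points, kernel bandwidths, threshold percentiles, simulation
#' parameters and the master seed. Values in the file override defaults;
#' arguments override both.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides of the top-level fields.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(path = NULL, ...) {
  cfg <- list(
    shape = c(120, 120), cell_size = 1000, seed = 1,
    n_source_points = 150,
    bandwidths = c(125000, 250000),
    percentiles = 10, sensitivity_percentiles = c(5, 20),
    resistance_mode = "literal",
    sim = list(generations = 200, n_reps = 5, max_cost_distance = 125000),
    sgd = list(n_classes = 8, n_perm = 199, min_n = 10, alpha = 0.05),
    sgd_epoch = "t0", sgd_bandwidth = 125000,
    run_sensitivity = FALSE
  )
  if (!is.null(path)) {
    filecfg <- yaml::read_yaml(path)
    cfg[names(filecfg)] <- filecfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$shape <- as.integer(unlist(cfg$shape))
  structure(cfg, class = "scenario_config")
}

write_metrics_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

epoch_metrics <- function(surface_grid, reference_grid, percentile,
                          landscape_cells, positive_only = TRUE) {
  b <- threshold_to_binary(surface_grid, reference_grid, percentile,
                           positive_only = positive_only)
  compute_metrics(label_patches(b), landscape_cells)
}

#' Run the full three-epoch connectivity and genetics analysis
#'
#' Orchestrates the whole chain on a synthetic scenario: expert-panel
#' aggregation and agreement; suitability-to-resistance conversion for the
#' first two epochs and risk-weighted projection for the third; source-point
#' seeding with a shared threshold; cumulative resistant kernels per epoch
#' and bandwidth; factorial least-cost-path networks with 10 km focal
#' smoothing; landscape pattern metrics and their relative changes between
#' epochs; replicated individual-based genetic simulations per epoch; local
#' genetic-diversity surfaces with a Mantel-correlogram-derived window; and
#' the diversity-vs-connectivity regressions. Rerunning with the same
#' config reproduces every output exactly.
#'
#' @param config A `scenario_config`.
#' @param out_dir Optional output directory; when given, every raster
#'   (ESRI ASCII), table (CSV) and a JSON manifest of seeds, parameters and
#'   file checksums are written there.
#' @param quiet Suppress stage messages.
#' @return A `scenario_result` list with all computed objects (see
#'   elements `agreement`, `suitability`, `resistance`, `sources`,
#'   `kernels`, `lcp`, `metrics`, `changes`, `sim_summaries`, `sgd`,
#'   `regression`, `manifest`).
#' @export
run_scenario <- function(config = scenario_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  epochs <- c("t0", "t1", "t2")

  say("stage synth: building %dx%d scenario (seed %d)",
      config$shape[1], config$shape[2], config$seed)
  scen <- build_scenario(shape = config$shape, cell_size = config$cell_size,
                         seed = config$seed)

  say("stage aggregate: expert panel")
  suit <- aggregate_ratings(scen$panel)
  agreement <- agreement_report(scen$panel)

  say("stage resistance")
  r_t0 <- build_resistance(scen$grids$t0, suit)
  r_t1 <- build_resistance(scen$grids$t1, suit)
  s_min <- min(suit$mean_suitability); s_max <- max(suit$mean_suitability)
  trans_suit <- suit$mean_suitability[
    suit$class_code == transition_code(scen$classes)]
  r_trans <- suitability_to_resistance(trans_suit, s_min, s_max)
  r_t2 <- project_future_resistance(r_t1, scen$risk, r_trans,
                                    mode = config$resistance_mode,
                                    epoch_label = "t2")
  resistance <- list(t0 = r_t0, t1 = r_t1, t2 = r_t2)

  say("stage sources: seeding %d points on t0", config$n_source_points)
  seed_pts <- derive_seed(config$seed, "sources")
  src_t0 <- seed_source_points(r_t0, config$n_source_points, seed = seed_pts)
  thr <- attr(src_t0, "threshold")
  sources <- list(t0 = src_t0,
                  t1 = reapply_threshold(r_t1, thr, seed = seed_pts),
                  t2 = reapply_threshold(r_t2, thr, seed = seed_pts))

  say("stage connect: kernels and least-cost paths")
  kernels <- list()
  for (e in epochs) {
    for (bw in config$bandwidths) {
      kernels[[sprintf("%s_%dkcu", e, bw / 1000)]] <-
        cumulative_resistant_kernel(resistance[[e]], sources[[e]], bw)
    }
  }
  lcp <- list(); lcp_smooth <- list()
  for (e in epochs) {
    lcp[[e]] <- factorial_least_cost_paths(resistance[[e]], sources[[e]])
    lcp_smooth[[e]] <- focal_mean(lcp[[e]]$raster, 10000)
  }

  say("stage metrics")
  landscape_cells <- sum(!is.na(r_t0$raster$values))
  pct_all <- config$percentiles
  if (isTRUE(config$run_sensitivity)) {
    pct_all <- sort(unique(c(pct_all, config$sensitivity_percentiles)))
  }
  metrics <- list()
  for (bw in config$bandwidths) {
    ref <- kernels[[sprintf("t0_%dkcu", bw / 1000)]]$raster
    for (p in pct_all) {
      for (e in epochs) {
        surf <- kernels[[sprintf("%s_%dkcu", e, bw / 1000)]]$raster
        m <- epoch_metrics(surf, ref, p, landscape_cells)
        metrics[[length(metrics) + 1L]] <-
          cbind(data.frame(epoch = e, surface = "kernel", bandwidth = bw,
                           percentile = p), m)
      }
    }
  }
  for (p in pct_all) {
    for (e in epochs) {
      m <- epoch_metrics(lcp_smooth[[e]], lcp_smooth$t0, p, landscape_cells)
      metrics[[length(metrics) + 1L]] <-
        cbind(data.frame(epoch = e, surface = "lcp", bandwidth = NA_real_,
                         percentile = p), m)
    }
  }
  metrics <- do.call(rbind, metrics)

  changes <- list()
  p0 <- config$percentiles[1L]
  for (bw in config$bandwidths) {
    km <- metrics[metrics$surface == "kernel" & metrics$bandwidth == bw &
                    metrics$percentile == p0, ]
    km <- km[match(epochs, km$epoch), ]
    for (col in c("pland", "lpi", "n_patches")) {
      changes[[length(changes) + 1L]] <- data.frame(
        metric = col, bandwidth = bw,
        change_t0_t1 = relative_change(km[[col]][1], km[[col]][2]),
        change_t1_t2 = relative_change(km[[col]][2], km[[col]][3]))
    }
  }
  lm_ <- metrics[metrics$surface == "lcp" & metrics$percentile == p0, ]
  lm_ <- lm_[match(epochs, lm_$epoch), ]
  changes[[length(changes) + 1L]] <- data.frame(
    metric = "correlation_length", bandwidth = NA_real_,
    change_t0_t1 = relative_change(lm_$correlation_length_m[1],
                                   lm_$correlation_length_m[2]),
    change_t1_t2 = relative_change(lm_$correlation_length_m[2],
                                   lm_$correlation_length_m[3]))
  changes <- do.call(rbind, changes)

  say("stage simulate: %d reps x %d generations per epoch",
      config$sim$n_reps, config$sim$generations)
  sims <- list(); sim_summaries <- list()
  for (e in epochs) {
    params <- sim_params(generations = config$sim$generations,
                         n_reps = config$sim$n_reps,
                         max_cost_distance = config$sim$max_cost_distance,
                         cell_size = config$cell_size,
                         seed = derive_seed(config$seed, paste0("sim_", e)))
    sims[[e]] <- run_simulation(sources[[e]], resistance[[e]], params)
    sim_summaries[[e]] <- cbind(data.frame(epoch = e),
                                summarise_runs(sims[[e]]))
  }
  sim_summaries <- do.call(rbind, sim_summaries)

  say("stage sgd: local diversity (epoch %s)", config$sgd_epoch)
  sgd <- run_sgd_stage(sims[[config$sgd_epoch]], config)

  say("stage regress")
  regression <- run_regression_stage(
    sims[[config$sgd_epoch]], sgd,
    resistance[[config$sgd_epoch]],
    kernels[[sprintf("%s_%dkcu", config$sgd_epoch,
                     config$sgd_bandwidth / 1000)]],
    lcp_smooth[[config$sgd_epoch]])

  result <- structure(
    list(config = config, scenario = scen, agreement = agreement,
         suitability = suit, resistance = resistance, sources = sources,
         kernels = kernels, lcp = lcp, lcp_smooth = lcp_smooth,
         metrics = metrics, changes = changes, sims = sims,
         sim_summaries = sim_summaries, sgd = sgd,
         regression = regression),
    class = "scenario_result")

  if (!is.null(out_dir)) {
    result$manifest <- write_scenario_outputs(result, out_dir)
  }
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t_start, "secs")))
  result
}

# Correlogram-sized local diversity across replicates of one epoch's runs.
run_sgd_stage <- function(runs, config) {
  cgs <- list(); n_used <- 0L
  for (r in seq_along(runs$final_states)) {
    st <- runs$final_states[[r]]
    if (st$extinct || length(st$loc) < 12L) next
    n_used <- n_used + 1L
    cost_r <- runs$cost[st$loc, st$loc]
    gen <- genetic_distances(st$geno)
    cgs[[n_used]] <- mantel_correlogram(
      gen, cost_r, n_classes = config$sgd$n_classes,
      n_perm = config$sgd$n_perm,
      seed = derive_seed(config$seed, paste0("mantel", r)))
  }
  if (!n_used) stop("sGD stage: no usable replicates", call. = FALSE)
  combined <- combine_correlograms(cgs)
  rng <- autocorrelation_range(combined, alpha = config$sgd$alpha)
  # fall back to half the dispersal threshold when no initial run of
  # significant classes exists
  radius <- if (rng > 0) rng / 2 else config$sim$max_cost_distance / 2
  local <- list()
  for (r in seq_along(runs$final_states)) {
    st <- runs$final_states[[r]]
    if (st$extinct || length(st$loc) < 12L) next
    cost_r <- runs$cost[st$loc, st$loc]
    ld <- local_diversity(st$geno, cost_r, radius,
                          min_n = config$sgd$min_n)
    ld$rep <- r
    local[[length(local) + 1L]] <- ld
  }
  list(correlograms = cgs, combined = combined, range = rng,
       radius = radius, local = local)
}

run_regression_stage <- function(runs, sgd, resistance, kernel, lcp_smooth) {
  tables <- list()
  li <- 0L
  for (r in seq_along(runs$final_states)) {
    st <- runs$final_states[[r]]
    if (st$extinct || length(st$loc) < 12L) next
    li <- li + 1L
    pts <- runs$sources[st$loc, ]
    tab <- assemble_predictor_table(pts, resistance, kernel, lcp_smooth,
                                    sgd$local[[li]])
    tab$rep <- r
    tables[[li]] <- tab
  }
  pooled <- do.call(rbind, tables)
  class(pooled) <- c("predictor_table", "data.frame")
  list(table = pooled,
       alleles = fit_diversity_models(pooled, "alleles"),
       ho = fit_diversity_models(pooled, "ho"))
}

write_scenario_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_raster <- function(grid, name) {
    p <- file.path(out_dir, name)
    write_raster(grid, p)
    files <<- c(files, p)
  }
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  for (e in names(result$resistance)) {
    put_raster(result$resistance[[e]]$raster,
               sprintf("Resistance_%s.asc", e))
  }
  for (nm in names(result$kernels)) {
    put_raster(result$kernels[[nm]]$raster, sprintf("kernel_%s.asc", nm))
  }
  for (e in names(result$lcp)) {
    put_raster(result$lcp[[e]]$raster, sprintf("LCP_%s.asc", e))
    put_raster(result$lcp_smooth[[e]], sprintf("LCP_%s_smoothed.asc", e))
  }
  for (e in names(result$sources)) {
    put_csv(as.data.frame(result$sources[[e]]),
            sprintf("sources_%s.csv", e))
  }
  put_csv(result$suitability, "suitability_table.csv")
  put_csv(result$metrics, "metrics.csv")
  put_csv(result$changes, "relative_changes.csv")
  put_csv(result$sim_summaries, "sim_summaries.csv")
  put_csv(result$sgd$combined, "mantel_correlogram.csv")
  put_csv(do.call(rbind, result$sgd$local), "local_diversity.csv")
  put_csv(rbind(cbind(response = "alleles",
                      result$regression$alleles$comparison),
                cbind(response = "ho", result$regression$ho$comparison)),
          "regression_comparison.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("connscape")),
    seed = result$config$seed,
    config = unclass(result$config),
    source_threshold = attr(result$sources$t0, "threshold"),
    n_sources = vapply(result$sources, nrow, 0L),
    files = basename(files),
    md5 = as.vector(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
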