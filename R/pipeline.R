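# End-to-end orchestration: simulate (or load) inputs, quantify, select
# seeds, build and filter the background, expand, score intermediates,
# null-test the topology, and extract percolation clusters, writing every
# intermediate artifact plus a run report.

#' Pipeline configuration
#'
#' Collects every stage threshold in one auditable place. When
#' `feature_tables` / `interactions` paths are `NULL`, inputs are
#' generated by the synthetic-data module under `generator`.
#'
#' @param generator A [generator_config()] for synthetic inputs.
#' @param feature_tables Optional character vector of feature-table CSV
#'   paths (one per experiment).
#' @param interactions Optional path to an interaction-record TSV.
#' @param rt_window,snr_min,mz_tol Peak-pair matching parameters
#'   ([match_peak_pairs()]).
#' @param min_id_score Identification-score gate
#'   ([aggregate_protein_ratios()]).
#' @param sd_multiple,min_consistent Seed selection thresholds
#'   ([select_seeds()]).
#' @param max_per_article Literature-filter threshold
#'   ([filter_articles()]).
#' @param max_intermediates Expansion path bound ([expand_subnetwork()]).
#' @param sig_threshold,high_threshold Enrichment tiers
#'   ([classify_score()]).
#' @param n_shuffles,swaps_per_edge Topology null parameters
#'   ([clustering_null_test()]).
#' @param k_values Clique sizes for percolation clustering.
#' @param module_size,module_density Planted dense-module parameters used
#'   when simulating.
#' @param rng_seed Master seed; all stage seeds derive from it.
#'
#' @return A validated list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            feature_tables = NULL,
                            interactions = NULL,
                            rt_window = 30, snr_min = 10, mz_tol = 0.05,
                            min_id_score = 60,
                            sd_multiple = 0.5, min_consistent = 2L,
                            max_per_article = 4L,
                            max_intermediates = 2L,
                            sig_threshold = 2, high_threshold = 3,
                            n_shuffles = 100L, swaps_per_edge = 10,
                            k_values = c(3L, 4L),
                            module_size = 12L, module_density = 0.9,
                            rng_seed = 1L) {
  cfg <- list(
    generator = generator,
    feature_tables = feature_tables,
    interactions = interactions,
    rt_window = check_number(rt_window, "rt_window", 0),
    snr_min = check_number(snr_min, "snr_min", 0),
    mz_tol = check_number(mz_tol, "mz_tol", 0),
    min_id_score = check_number(min_id_score, "min_id_score", 0),
    sd_multiple = check_number(sd_multiple, "sd_multiple", 0),
    min_consistent = check_count(min_consistent, "min_consistent", 1L),
    max_per_article = check_count(max_per_article, "max_per_article", 0L),
    max_intermediates = check_count(max_intermediates,
                                    "max_intermediates", 0L),
    sig_threshold = check_number(sig_threshold, "sig_threshold"),
    high_threshold = check_number(high_threshold, "high_threshold"),
    n_shuffles = check_count(n_shuffles, "n_shuffles", 1L),
    swaps_per_edge = check_number(swaps_per_edge, "swaps_per_edge", 0),
    k_values = vapply(k_values, check_count, integer(1), name = "k_values",
                      min = 2L),
    module_size = check_count(module_size, "module_size", 0L),
    module_density = check_fraction(module_density, "module_density"),
    rng_seed = check_count(rng_seed, "rng_seed", 0L)
  )
  if (!is.null(generator) && !inherits(generator, "generator_config"))
    stop_param("'generator' must be a generator_config()")
  if (cfg$sig_threshold > cfg$high_threshold)
    stop_param("'sig_threshold' must not exceed 'high_threshold'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a JSON file
#'
#' Top-level keys override [pipeline_config()] defaults; the `generator`
#' key (an object) overrides [generator_config()] defaults.
#'
#' @param path JSON file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen_args <- raw$generator
  raw$generator <- NULL
  gen <- do.call(generator_config, as.list(gen_args))
  do.call(pipeline_config, c(list(generator = gen), raw))
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[presynet] ", fmt), ...))
}

run_stage <- function(name, outdir, verbose, expr) {
  pipeline_log(verbose, "stage %s", name)
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order -- simulate/load, quantify, select seeds,
#' consolidate and filter the background, expand the seed subnetwork,
#' score intermediates, null-test the clustering coefficient, extract
#' k-clique percolation clusters -- writing every intermediate artifact
#' into `outdir` plus a final `run_report.json`. Identical configuration
#' and seed produce byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param verbose Log per-stage progress messages.
#'
#' @return (Invisibly) a list with the in-memory stage results: `truth`,
#'   `features`, `ratio_matrix`, `seeds`, `background`, `filtered`,
#'   `subnetwork`, `enrichment`, `topology`, `clusters`, and `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile(),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- derive_seeds(config$rng_seed, 6L)

  # --- simulate or load inputs -------------------------------------------
  truth <- NULL
  if (is.null(config$feature_tables) || is.null(config$interactions)) {
    sim <- run_stage("simulate", outdir, verbose, {
      gcfg <- config$generator
      records <- gen_background(gcfg, rng_seed = stage_seeds[1])
      bg_nodes <- attr(records, "nodes")
      universe <- if (length(bg_nodes) >= gcfg$n_proteins)
        sort(sample(sort(unique(c(records$node_a, records$node_b))),
                    gcfg$n_proteins))
      else NULL
      truth <- plant_regulation(gcfg, protein_ids = universe,
                                rng_seed = stage_seeds[2])
      if (config$module_size >= 2L && !is.null(universe)) {
        reg <- truth$regulated_proteins$protein_id
        n_reg_in <- min(length(reg), ceiling(config$module_size / 2))
        others <- setdiff(sort(unique(c(records$node_a, records$node_b))),
                          truth$protein_ids)
        mod_nodes <- c(sample(reg, n_reg_in),
                       sample(others, config$module_size - n_reg_in))
        pm <- plant_module(records, length(mod_nodes),
                           config$module_density,
                           rng_seed = stage_seeds[3], nodes = mod_nodes,
                           truth = truth)
        records <- pm$records
        truth <- pm$truth
      }
      tables <- gen_quant_experiments(gcfg, truth,
                                      rng_seed = stage_seeds[4])
      for (nm in names(tables))
        write_feature_table(tables[[nm]],
                            file.path(outdir,
                                      sprintf("features_%s.csv", nm)))
      write_interactions(records, file.path(outdir, "interactions.tsv"))
      write_truth(truth, file.path(outdir, "planted_truth.json"))
      list(records = records, tables = tables, truth = truth)
    })
    records <- sim$records
    tables <- sim$tables
    truth <- sim$truth
  } else {
    loaded <- run_stage("load", outdir, verbose, {
      list(records = read_interactions(config$interactions),
           tables = lapply(config$feature_tables, read_feature_table))
    })
    records <- loaded$records
    tables <- loaded$tables
  }

  # --- quantify -----------------------------------------------------------
  prm <- run_stage("quantify", outdir, verbose, {
    prm <- quantify_experiments(tables, rt_window = config$rt_window,
                                snr_min = config$snr_min,
                                mz_tol = config$mz_tol,
                                min_id_score = config$min_id_score)
    write_ratio_matrix(prm, file.path(outdir, "protein_ratios.tsv"))
    prm
  })
  pipeline_log(verbose, "quantified %d proteins in %d experiments",
               nrow(prm$ratios), ncol(prm$ratios))

  # --- seeds --------------------------------------------------------------
  seeds <- run_stage("seeds", outdir, verbose, {
    seeds <- select_seeds(prm, sd_multiple = config$sd_multiple,
                          min_consistent = config$min_consistent)
    write_seed_list(seeds, file.path(outdir, "seed_list.tsv"))
    seeds
  })
  pipeline_log(verbose, "seed list: %d proteins (%d down, %d up)",
               nrow(seeds), sum(seeds$direction == "down"),
               sum(seeds$direction == "up"))
  if (nrow(seeds) == 0L)
    warning("seed list is empty; downstream stages will be degenerate",
            call. = FALSE)

  # --- background ---------------------------------------------------------
  nets <- run_stage("background", outdir, verbose, {
    raw_net <- consolidate(records)
    filtered <- filter_articles(raw_net,
                                max_per_article = config$max_per_article)
    write_network(filtered, file.path(outdir, "background"))
    list(raw = raw_net, filtered = filtered)
  })
  pipeline_log(verbose,
               "background: %d nodes / %d links; filtered: %d nodes / %d links",
               length(nets$raw$nodes), nrow(nets$raw$edges),
               length(nets$filtered$nodes), nrow(nets$filtered$edges))

  # --- expand -------------------------------------------------------------
  sub <- run_stage("expand", outdir, verbose, {
    if (nrow(seeds) == 0L) {
      sub <- structure(list(seed_nodes = character(0),
                            intermediate_nodes = character(0),
                            edges = data.frame(node_a = character(0),
                                               node_b = character(0),
                                               stringsAsFactors = FALSE),
                            all_seeds = character(0),
                            unmapped_seeds = character(0),
                            max_intermediates = config$max_intermediates),
                       class = "subnetwork")
    } else {
      sub <- expand_subnetwork(seeds, nets$filtered,
                               max_intermediates = config$max_intermediates)
    }
    write_subnetwork(sub, file.path(outdir, "subnetwork"))
    sub
  })
  ssum <- subnetwork_summary(sub)
  pipeline_log(verbose,
               "subnetwork: %d interactions among %d seeds via %d intermediates",
               ssum$n_edges, ssum$n_seed_connected, ssum$n_intermediates)

  # --- score --------------------------------------------------------------
  enr <- run_stage("score", outdir, verbose, {
    enr <- enrichment_table(sub$intermediate_nodes, seeds, nets$filtered,
                            sig_threshold = config$sig_threshold,
                            high_threshold = config$high_threshold)
    write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    enr
  })
  tiers <- tier_counts(enr)
  pipeline_log(verbose, "%d significant intermediates (score>%g), %d highly significant (score>%g)",
               tiers$n_significant, config$sig_threshold,
               tiers$n_highly_significant, config$high_threshold)

  # --- nulltest -----------------------------------------------------------
  topo <- run_stage("nulltest", outdir, verbose, {
    g <- as_igraph(sub)
    if (igraph::ecount(g) < 2L || igraph::vcount(g) == 0L) {
      warning("subnetwork too small for a topology null test",
              call. = FALSE)
      NULL
    } else {
      topo <- clustering_null_test(g, n_shuffles = config$n_shuffles,
                                   swaps_per_edge = config$swaps_per_edge,
                                   rng_seed = stage_seeds[5])
      write_topology_report(topo, file.path(outdir, "topology.json"))
      topo
    }
  })

  # --- clusters -----------------------------------------------------------
  clusters <- run_stage("clusters", outdir, verbose, {
    g <- as_igraph(sub)
    sets <- lapply(config$k_values, function(k)
      percolation_clusters(g, k))
    write_clusters(sets, file.path(outdir, "clusters.tsv"))
    sets
  })
  crep <- cluster_report(clusters)
  pipeline_log(verbose, "clusters: %s", crep$summary_line)

  # --- report -------------------------------------------------------------
  report <- list(
    software = list(package = "presynet",
                    version = as.character(utils::packageVersion("presynet"))),
    config = config_echo(config),
    counts = list(
      n_experiments = length(tables),
      n_features = sum(vapply(tables, nrow, integer(1))),
      n_proteins_identified =
        length(unique(unlist(lapply(tables, `[[`, "protein_id")))),
      n_proteins_quantified = nrow(prm$ratios),
      n_seeds = nrow(seeds),
      n_seeds_down = sum(seeds$direction == "down"),
      n_seeds_up = sum(seeds$direction == "up"),
      background_nodes = length(nets$raw$nodes),
      background_links = nrow(nets$raw$edges),
      filtered_nodes = length(nets$filtered$nodes),
      filtered_links = nrow(nets$filtered$edges),
      articles_excluded =
        length(attr(nets$filtered, "excluded_articles"))
    ),
    subnetwork = ssum,
    enrichment = tiers,
    topology = if (is.null(topo)) NULL
               else list(c_observed = topo$c_observed,
                         null_mean = topo$null_mean,
                         p_empirical = topo$p_empirical,
                         n_shuffles = topo$n_shuffles),
    clusters = as.list(crep$counts),
    cluster_summary = crep$summary_line
  )
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, features = tables, ratio_matrix = prm,
                 seeds = seeds, background = nets$raw,
                 filtered = nets$filtered, subnetwork = sub,
                 enrichment = enr, topology = topo, clusters = clusters,
                 report = report, outdir = outdir))
}

# Serializable echo of the configuration (paths and thresholds only).
config_echo <- function(config) {
  out <- unclass(config)
  out$generator <- unclass(out$generator)
  out
}
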