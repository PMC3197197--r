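# Synthetic-data module: seeded generators for (a) provenance-annotated
# protein-protein interaction backgrounds with plantable dense modules and
# (b) peptide-level light/heavy LC-MS feature tables with planted protein
# regulation, so that every downstream stage can be checked against ground
# truth.

#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic proteomics experiment and of the
#' synthetic interaction background. Defaults mirror a five-experiment
#' forward/reverse isotope-labeling study in which 175 proteins are
#' identified, 143 pass the identification-score gate in every peptide and
#' are quantified, and 30 (23 down, 7 up) are truly regulated.
#'
#' @param n_proteins Number of identified proteins in the universe.
#' @param n_quantified Number of proteins whose peptides all pass the
#'   identification-score gate (the quantifiable subset).
#' @param n_regulated Number of truly regulated proteins (planted).
#' @param n_down Number of regulated proteins that are downregulated; the
#'   remaining `n_regulated - n_down` are upregulated.
#' @param n_experiments Number of labeling experiments.
#' @param labeling_schedule Character vector of `"forward"` / `"reverse"`
#'   flags, one per experiment. Forward means treatment = heavy label.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise applied to each peptide pair's intensity ratio.
#' @param log2_fc_range Range of planted absolute log2 fold-changes;
#'   magnitudes are drawn uniformly from this interval.
#' @param peptides_range Integer range (min, max) of tryptic peptides
#'   generated per protein.
#' @param snr_decoy_frac Fraction of features whose signal-to-noise is drawn
#'   below the S/N acceptance gate (decoys exercising the S/N filter).
#' @param id_score_range Identification-score range for gate-passing
#'   peptides.
#' @param low_score_range Identification-score range for the sub-gate
#'   peptide planted in each non-quantifiable protein.
#' @param background_n_nodes Number of nodes in the synthetic background
#'   network.
#' @param background_mean_degree Target mean degree of the background.
#' @param n_articles Number of literature articles providing interaction
#'   records.
#' @param frac_highthroughput_articles Fraction of articles flagged
#'   high-throughput; exactly these articles contribute >= 5 records each,
#'   all others contribute <= 4.
#' @param mixed_support_frac Fraction of low-throughput records that
#'   re-report an interaction already covered by a high-throughput article
#'   (mixed-provenance edges that must survive the literature filter).
#' @param rng_seed Integer seed; identical configurations and seeds
#'   reproduce all generator outputs exactly.
#'
#' @return A list of validated settings with class `"generator_config"`.
#' @seealso [gen_background()], [plant_regulation()],
#'   [gen_quant_experiments()]
#' @export
generator_config <- function(n_proteins = 175L,
                             n_quantified = 143L,
                             n_regulated = 30L,
                             n_down = 23L,
                             n_experiments = 5L,
                             labeling_schedule = c("forward", "reverse",
                                                   "forward", "reverse",
                                                   "forward"),
                             noise_cv = 0.15,
                             log2_fc_range = c(1, 2),
                             peptides_range = c(1L, 5L),
                             snr_decoy_frac = 0.02,
                             id_score_range = c(60, 130),
                             low_score_range = c(20, 59),
                             background_n_nodes = 3000L,
                             background_mean_degree = 8,
                             n_articles = 2500L,
                             frac_highthroughput_articles = 0.06,
                             mixed_support_frac = 0.25,
                             rng_seed = 1L) {
  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins", 1L),
    n_quantified = check_count(n_quantified, "n_quantified", 1L),
    n_regulated = check_count(n_regulated, "n_regulated", 0L),
    n_down = check_count(n_down, "n_down", 0L),
    n_experiments = check_count(n_experiments, "n_experiments", 1L),
    labeling_schedule = as.character(labeling_schedule),
    noise_cv = check_number(noise_cv, "noise_cv", 0),
    log2_fc_range = sort(as.numeric(log2_fc_range)),
    peptides_range = as.integer(peptides_range),
    snr_decoy_frac = check_fraction(snr_decoy_frac, "snr_decoy_frac"),
    id_score_range = as.numeric(id_score_range),
    low_score_range = as.numeric(low_score_range),
    background_n_nodes = check_count(background_n_nodes,
                                     "background_n_nodes", 0L),
    background_mean_degree = check_number(background_mean_degree,
                                          "background_mean_degree", 0),
    n_articles = check_count(n_articles, "n_articles", 1L),
    frac_highthroughput_articles =
      check_fraction(frac_highthroughput_articles,
                     "frac_highthroughput_articles"),
    mixed_support_frac = check_fraction(mixed_support_frac,
                                        "mixed_support_frac"),
    rng_seed = check_count(rng_seed, "rng_seed", 0L)
  )
  if (cfg$n_down > cfg$n_regulated)
    stop_param("'n_down' must not exceed 'n_regulated'")
  if (cfg$n_regulated > cfg$n_quantified)
    stop_param("'n_regulated' must not exceed 'n_quantified'")
  if (cfg$n_quantified > cfg$n_proteins)
    stop_param("'n_quantified' must not exceed 'n_proteins'")
  if (length(cfg$labeling_schedule) != cfg$n_experiments)
    stop_param("'labeling_schedule' length must equal 'n_experiments'")
  if (!all(cfg$labeling_schedule %in% c("forward", "reverse")))
    stop_param("'labeling_schedule' entries must be 'forward' or 'reverse'")
  if (length(cfg$peptides_range) != 2L || cfg$peptides_range[1] < 1L ||
      cfg$peptides_range[2] < cfg$peptides_range[1])
    stop_param("'peptides_range' must be an increasing positive pair")
  if (length(cfg$log2_fc_range) != 2L || cfg$log2_fc_range[1] <= 0)
    stop_param("'log2_fc_range' must be a positive pair")
  class(cfg) <- "generator_config"
  cfg
}

empty_interactions <- function() {
  data.frame(node_a = character(0), node_b = character(0),
             dataset = character(0), article_id = character(0),
             stringsAsFactors = FALSE)
}

# Chung-Lu style edge sampling: endpoint propensities drawn log-normally so
# the degree distribution is right-skewed like curated PPI data; self-loops
# and duplicate edges rejected.
sample_unique_edges <- function(n_nodes, n_edges) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop_param("requested mean degree exceeds a simple graph's capacity")
  w <- stats::rlnorm(n_nodes, meanlog = 0, sdlog = 1)
  keys <- character(0)
  while (length(keys) < n_edges) {
    batch <- max(2L * (n_edges - length(keys)), 1000L)
    a <- sample.int(n_nodes, batch, replace = TRUE, prob = w)
    b <- sample.int(n_nodes, batch, replace = TRUE, prob = w)
    ok <- a != b
    keys <- unique(c(keys, edge_key(a[ok], b[ok])))
  }
  keys[seq_len(n_edges)]
}

#' Generate a synthetic interaction background with article provenance
#'
#' Draws a simple undirected random graph with heterogeneous degrees
#' (configuration-model style endpoint propensities) and annotates every
#' edge with one or more literature article identifiers. A configured
#' fraction of articles is flagged high-throughput: exactly those articles
#' contribute five or more interaction records each, all remaining articles
#' contribute at most four, and a configured fraction of low-throughput
#' records re-reports edges already covered by a high-throughput article so
#' that the downstream literature filter sees mixed-provenance edges.
#'
#' @param config A [generator_config()].
#' @param rng_seed Seed used for this generator; defaults to the
#'   configuration's seed.
#'
#' @return A data.frame of interaction records with columns `node_a`,
#'   `node_b`, `dataset`, `article_id`, plus attributes
#'   `highthroughput_articles` (the planted flags) and `nodes` (the full
#'   node universe).
#' @export
gen_background <- function(config, rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "generator_config"))
  n0 <- config$background_n_nodes
  if (n0 == 0L) {
    out <- empty_interactions()
    attr(out, "highthroughput_articles") <- character(0)
    attr(out, "nodes") <- character(0)
    return(out)
  }
  set.seed(as.integer(rng_seed))
  nodes <- sprintf("G%05d", seq_len(n0))
  m <- max(1L, round(n0 * config$background_mean_degree / 2))
  keys <- sample_unique_edges(n0, m)

  n_ht <- round(config$frac_highthroughput_articles * config$n_articles)
  n_lt <- config$n_articles - n_ht
  article_ids <- sprintf("ART%05d", seq_len(config$n_articles))
  ht_ids <- if (n_ht > 0) sort(sample(article_ids, n_ht)) else character(0)
  lt_ids <- setdiff(article_ids, ht_ids)

  counts_lt <- if (n_lt > 0) sample(1:4, n_lt, replace = TRUE) else integer(0)

  if (n_ht == 0L) {
    # Every edge needs low-throughput coverage; top counts up (cap 4).
    deficit <- m - sum(counts_lt)
    if (deficit > 0) {
      if (4L * n_lt < m)
        stop_param("too few articles to cover all edges with <= 4 records each")
      room <- 4L - counts_lt
      take <- pmin(room, pmax(0L, deficit - c(0L, cumsum(room)[-n_lt])))
      counts_lt <- counts_lt + take
    }
    fresh_n <- m
    n_mixed <- sum(counts_lt) - m
    ht_edge_keys <- character(0)
  } else {
    r_lt <- sum(counts_lt)
    n_mixed <- floor(config$mixed_support_frac * r_lt)
    fresh_n <- r_lt - n_mixed
    # High-throughput articles need >= 5 edges each.
    if (fresh_n > m - 5L * n_ht) {
      fresh_n <- max(0L, m - 5L * n_ht)
      n_mixed <- r_lt - fresh_n
    }
    if (m - fresh_n < 5L * n_ht)
      stop_param(paste("background too small for the requested number of",
                       "high-throughput articles"))
  }

  perm <- sample(keys)
  fresh_keys <- if (fresh_n > 0) perm[seq_len(fresh_n)] else character(0)
  if (n_ht > 0L) {
    ht_edge_keys <- perm[(fresh_n + 1L):m]
    if (n_mixed > length(ht_edge_keys))
      stop_param("not enough high-throughput edges for mixed support")
    mixed_keys <- if (n_mixed > 0) sample(ht_edge_keys, n_mixed)
                  else character(0)
  } else {
    mixed_keys <- if (n_mixed > 0) sample(keys, n_mixed, replace = n_mixed > m)
                  else character(0)
  }

  # Low-throughput records: planted counts per article, slots filled with a
  # permutation of fresh + mixed edges (unique (edge, article) pairs).
  lt_records <- NULL
  if (n_lt > 0 && sum(counts_lt) > 0) {
    lt_slots <- rep(lt_ids, times = counts_lt)
    slot_edges <- sample(c(fresh_keys, mixed_keys))
    stopifnot(length(slot_edges) == length(lt_slots))
    if (n_ht == 0L) {
      # mixed keys may collide with fresh keys within one article; nudge
      dup <- duplicated(paste(lt_slots, slot_edges))
      tries <- 0L
      while (any(dup) && tries < 100L) {
        slot_edges[dup] <- sample(keys, sum(dup), replace = TRUE)
        dup <- duplicated(paste(lt_slots, slot_edges))
        tries <- tries + 1L
      }
      keep <- !dup
      lt_slots <- lt_slots[keep]
      slot_edges <- slot_edges[keep]
    }
    lt_records <- data.frame(key = slot_edges, article_id = lt_slots,
                             dataset = "SYN_LIT", stringsAsFactors = FALSE)
  }

  ht_records <- NULL
  if (n_ht > 0L) {
    n_ht_edges <- length(ht_edge_keys)
    extra <- n_ht_edges - 5L * n_ht
    counts_ht <- 5L + tabulate(sample.int(n_ht, extra, replace = TRUE), n_ht)
    ht_slots <- rep(ht_ids, times = counts_ht)
    ht_records <- data.frame(key = ht_edge_keys, article_id = ht_slots,
                             dataset = "SYN_SCREEN", stringsAsFactors = FALSE)
  }

  rec <- rbind(lt_records, ht_records)
  ends <- split_edge_key(rec$key)
  out <- data.frame(node_a = nodes[as.integer(ends[, 1])],
                    node_b = nodes[as.integer(ends[, 2])],
                    dataset = rec$dataset,
                    article_id = rec$article_id,
                    stringsAsFactors = FALSE)
  out <- out[order(out$article_id, out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "highthroughput_articles") <- ht_ids
  attr(out, "nodes") <- nodes
  out
}

#' Plant a dense module into an interaction record list
#'
#' Selects (or accepts) a set of module nodes and adds interaction records
#' until the module's induced subgraph reaches the requested edge density.
#' Added records carry fresh synthetic low-throughput article identifiers
#' (at most four records per article) so they survive the literature
#' filter.
#'
#' @param records Interaction records (`node_a`, `node_b`, `dataset`,
#'   `article_id`).
#' @param module_size Number of module nodes (ignored when `nodes` given).
#' @param density Target edge density of the induced subgraph in `[0, 1]`;
#'   `0` leaves the records unchanged.
#' @param rng_seed Integer seed.
#' @param nodes Optional explicit module node names.
#' @param truth Optional planted-truth object to update in place.
#'
#' @return A list with elements `records` (augmented record data.frame) and
#'   `truth` (a planted-truth list whose `planted_module_nodes` field names
#'   the module).
#' @export
plant_module <- function(records, module_size, density, rng_seed,
                         nodes = NULL, truth = NULL) {
  density <- check_fraction(density, "density")
  all_nodes <- sort(unique(c(records$node_a, records$node_b)))
  if (is.null(nodes)) {
    module_size <- check_count(module_size, "module_size", 2L)
    if (module_size > length(all_nodes))
      stop_param("'module_size' exceeds the number of nodes in 'records'")
    set.seed(as.integer(rng_seed))
    nodes <- sample(all_nodes, module_size)
  } else {
    set.seed(as.integer(rng_seed))
    if (!all(nodes %in% all_nodes))
      stop_param("explicit module 'nodes' must be existing network nodes")
  }
  nodes <- sort(unique(nodes))
  if (is.null(truth)) {
    truth <- list(regulated_proteins = NULL, planted_module_nodes = nodes,
                  rng_seed = as.integer(rng_seed))
    class(truth) <- "planted_truth"
  } else {
    truth$planted_module_nodes <- nodes
  }

  if (density > 0 && length(nodes) >= 2L) {
    pairs <- combn(nodes, 2L)
    target <- ceiling(density * ncol(pairs))
    existing <- unique(edge_key(records$node_a, records$node_b))
    pair_keys <- edge_key(pairs[1, ], pairs[2, ])
    missing <- which(!(pair_keys %in% existing))
    need <- target - (ncol(pairs) - length(missing))
    if (need > 0) {
      add <- if (need >= length(missing)) missing
             else sample(missing, need)
      art <- sprintf("SYNMOD%04d", ceiling(seq_along(add) / 4))
      new <- data.frame(node_a = pairs[1, add], node_b = pairs[2, add],
                        dataset = "SYN_PLANT", article_id = art,
                        stringsAsFactors = FALSE)
      atts <- attributes(records)
      records <- rbind(records, new)
      rownames(records) <- NULL
      attr(records, "highthroughput_articles") <- atts$highthroughput_articles
      attr(records, "nodes") <- atts$nodes
    }
  }
  list(records = records, truth = truth)
}

#' Plant protein regulation ground truth
#'
#' Chooses the quantifiable protein subset, the regulated proteins, their
#' directions, and their true fold-changes. Downregulated proteins get
#' `2^-u` and upregulated `2^u` with `u` uniform on
#' `config$log2_fc_range`; unregulated proteins have true fold-change 1.
#'
#' @param config A [generator_config()].
#' @param protein_ids Optional explicit protein universe (e.g. node names
#'   of a background network); defaults to `PROT001`, `PROT002`, ...
#' @param rng_seed Seed; defaults to the configuration's seed.
#'
#' @return A `"planted_truth"` list with fields `regulated_proteins` (a
#'   data.frame of `protein_id`, `direction`, `log2_fc`, `fold_change`),
#'   `protein_ids`, `quantified_ids`, `planted_module_nodes`, `rng_seed`.
#' @export
plant_regulation <- function(config, protein_ids = NULL,
                             rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(rng_seed))
  if (is.null(protein_ids)) {
    protein_ids <- sprintf("PROT%03d", seq_len(config$n_proteins))
  } else {
    protein_ids <- as.character(protein_ids)
    if (length(protein_ids) != config$n_proteins)
      stop_param("'protein_ids' length must equal config$n_proteins")
    if (anyDuplicated(protein_ids))
      stop_param("'protein_ids' must be unique")
  }
  quantified <- sort(sample(protein_ids, config$n_quantified))
  regulated <- sort(sample(quantified, config$n_regulated))
  down <- if (config$n_down > 0) sample(regulated, config$n_down)
          else character(0)
  direction <- ifelse(regulated %in% down, "down", "up")
  mag <- runif(length(regulated), config$log2_fc_range[1],
               config$log2_fc_range[2])
  log2_fc <- ifelse(direction == "down", -mag, mag)
  truth <- list(
    regulated_proteins = data.frame(protein_id = regulated,
                                    direction = direction,
                                    log2_fc = log2_fc,
                                    fold_change = 2^log2_fc,
                                    stringsAsFactors = FALSE),
    protein_ids = protein_ids,
    quantified_ids = quantified,
    planted_module_nodes = character(0),
    rng_seed = as.integer(rng_seed)
  )
  class(truth) <- "planted_truth"
  truth
}

AA20 <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]

# One peptide catalog per protein universe: the same tryptic peptides recur
# in every experiment, as they would in repeated runs of one digest.
build_peptide_catalog <- function(config, truth) {
  ids <- truth$protein_ids
  npep <- sample(seq(config$peptides_range[1], config$peptides_range[2]),
                 length(ids), replace = TRUE)
  protein_id <- rep(ids, npep)
  n <- length(protein_id)
  label_sites <- sample(1:2, n, replace = TRUE)
  # Tryptic peptides end in R (1 labeled site: N-terminus) or K (2 sites:
  # N-terminus + C-terminal lysine).
  body_len <- sample(6:11, n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(paste(sample(AA20, body_len[i], replace = TRUE), collapse = ""),
           if (label_sites[i] == 2L) "K" else "R")
  }, character(1))
  seqs <- make.unique(seqs, sep = "")
  charge <- sample(1:2, n, replace = TRUE)
  mz_light <- runif(n, 300, 1200)
  # Proteins outside the quantifiable subset carry one sub-gate peptide.
  gate_fail <- !(truth$protein_ids %in% truth$quantified_ids)
  first_row <- match(ids, protein_id)
  low_score <- logical(n)
  low_score[first_row[gate_fail]] <- TRUE
  data.frame(protein_id = protein_id, peptide_seq = seqs,
             label_sites = label_sites, charge = charge,
             mz_light = mz_light, low_score = low_score,
             stringsAsFactors = FALSE)
}

#' Generate light/heavy feature tables for every experiment
#'
#' Each protein contributes 1-5 tryptic-style peptides (fixed across
#' experiments, as in repeated runs of one digest); each peptide yields a
#' light/heavy feature pair whose m/z separation is
#' `4 * label_sites / charge` (the 2/4/8 Da pair classes at charges 1-2),
#' whose retention times differ by less than 30 s, and whose intensity
#' ratio is the protein's true fold-change perturbed by multiplicative
#' log-normal noise with the configured CV. In reverse-labeled experiments
#' the light/heavy roles of treatment and control swap, so the raw
#' heavy/light ratio inverts while the treatment/control ratio is
#' preserved. A configured fraction of features receives sub-gate
#' signal-to-noise (decoys); non-quantifiable proteins carry one peptide
#' whose identification score falls below the gate in every experiment.
#'
#' @param config A [generator_config()].
#' @param truth A planted-truth object from [plant_regulation()].
#' @param rng_seed Seed; defaults to the configuration's seed.
#'
#' @return A named list of feature-table data.frames, one per experiment,
#'   with columns `experiment_id`, `direction`, `protein_id`,
#'   `peptide_seq`, `label_sites`, `charge`, `channel`, `mz`,
#'   `rt_seconds`, `intensity`, `snr`, `id_score`.
#' @export
gen_quant_experiments <- function(config, truth,
                                  rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "generator_config"),
            inherits(truth, "planted_truth"))
  if (length(config$labeling_schedule) != config$n_experiments)
    stop_param("'labeling_schedule' length must equal 'n_experiments'")
  set.seed(as.integer(rng_seed))
  cat_df <- build_peptide_catalog(config, truth)
  fc <- setNames(rep(1, length(truth$protein_ids)), truth$protein_ids)
  if (!is.null(truth$regulated_proteins) &&
      nrow(truth$regulated_proteins) > 0)
    fc[truth$regulated_proteins$protein_id] <-
      truth$regulated_proteins$fold_change
  sigma <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  n <- nrow(cat_df)
  sep <- 4 * cat_df$label_sites / cat_df$charge

  out <- vector("list", config$n_experiments)
  names(out) <- sprintf("EXP%d", seq_len(config$n_experiments))
  for (e in seq_len(config$n_experiments)) {
    dir_e <- config$labeling_schedule[e]
    base_ratio <- fc[cat_df$protein_id]
    if (dir_e == "reverse") base_ratio <- 1 / base_ratio
    noise <- if (sigma > 0) exp(rnorm(n, 0, sigma)) else rep(1, n)
    ratio_hl <- base_ratio * noise
    light_int <- rlnorm(n, meanlog = log(2e5), sdlog = 0.7)
    heavy_int <- light_int * ratio_hl
    rt_light <- runif(n, 1200, 2700)
    rt_heavy <- rt_light + runif(n, -14, 14)
    snr_draw <- function(k) {
      decoy <- runif(k) < config$snr_decoy_frac
      ifelse(decoy, runif(k, 2, 9.5), runif(k, 10.5, 90))
    }
    id_score <- ifelse(cat_df$low_score,
                       runif(n, config$low_score_range[1],
                             config$low_score_range[2]),
                       runif(n, config$id_score_range[1],
                             config$id_score_range[2]))
    tab <- data.frame(
      experiment_id = names(out)[e],
      direction = dir_e,
      protein_id = rep(cat_df$protein_id, 2L),
      peptide_seq = rep(cat_df$peptide_seq, 2L),
      label_sites = rep(cat_df$label_sites, 2L),
      charge = rep(cat_df$charge, 2L),
      channel = rep(c("light", "heavy"), each = n),
      mz = c(cat_df$mz_light, cat_df$mz_light + sep),
      rt_seconds = c(rt_light, rt_heavy),
      intensity = c(light_int, heavy_int),
      snr = c(snr_draw(n), snr_draw(n)),
      id_score = rep(id_score, 2L),
      stringsAsFactors = FALSE
    )
    tab <- tab[order(tab$protein_id, tab$peptide_seq, tab$channel), ,
               drop = FALSE]
    rownames(tab) <- NULL
    out[[e]] <- tab
  }
  out
}

#' Read or write a feature table as CSV
#'
#' The on-disk schema is `experiment_id, direction, protein_id,
#' peptide_seq, label_sites, charge, channel, mz, rt_seconds, intensity,
#' snr, id_score`.
#'
#' @param table A feature-table data.frame.
#' @param path File path.
#' @return `read_feature_table` returns the data.frame;
#'   `write_feature_table` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("experiment_id", "direction", "protein_id", "peptide_seq",
            "label_sites", "charge", "channel", "mz", "rt_seconds",
            "intensity", "snr", "id_score")
  stopifnot(all(cols %in% names(table)))
  write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read or write interaction records as TSV
#'
#' Schema: `node_a, node_b, dataset, article_id`.
#'
#' @param records Interaction-record data.frame.
#' @param path File path.
#' @return `read_interactions` returns the data.frame;
#'   `write_interactions` returns `path` invisibly.
#' @export
write_interactions <- function(records, path) {
  cols <- c("node_a", "node_b", "dataset", "article_id")
  stopifnot(all(cols %in% names(records)))
  write.table(records[, cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read or write planted ground truth as JSON
#'
#' @param truth A `"planted_truth"` object.
#' @param path File path.
#' @return `read_truth` returns the `"planted_truth"` object;
#'   `write_truth` returns `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(truth$regulated_proteins) &&
      length(truth$regulated_proteins) > 0)
    truth$regulated_proteins <- as.data.frame(truth$regulated_proteins,
                                              stringsAsFactors = FALSE)
  truth$planted_module_nodes <- as.character(truth$planted_module_nodes)
  class(truth) <- "planted_truth"
  truth
}
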