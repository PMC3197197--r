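# Synthetic-data generators: seeded determinism, article provenance,
# planted modules, and noiseless label-swap construction.

test_that("generator_config validates its invariants", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_down = 31, n_regulated = 30), "n_down")
  expect_error(generator_config(n_regulated = 200, n_quantified = 143),
               "n_regulated")
  expect_error(generator_config(n_quantified = 200, n_proteins = 175),
               "n_quantified")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
  expect_error(generator_config(labeling_schedule = c("forward", "x"),
                                n_experiments = 2), "forward")
  expect_error(generator_config(labeling_schedule = "forward",
                                n_experiments = 3), "labeling_schedule")
})

test_that("an empty background request yields an empty record list", {
  cfg <- generator_config(background_n_nodes = 0)
  rec <- gen_background(cfg)
  expect_equal(nrow(rec), 0L)
  expect_identical(attr(rec, "highthroughput_articles"), character(0))
})

test_that("background generation is deterministic under a fixed seed", {
  cfg <- generator_config(background_n_nodes = 500,
                          background_mean_degree = 8,
                          n_articles = 100,
                          frac_highthroughput_articles = 0.2,
                          rng_seed = 1)
  r1 <- gen_background(cfg)
  r2 <- gen_background(cfg)
  expect_identical(r1, r2)
})

test_that("exactly the flagged high-throughput articles have >= 5 records", {
  cfg <- generator_config(background_n_nodes = 500,
                          background_mean_degree = 8,
                          n_articles = 100,
                          frac_highthroughput_articles = 0.2,
                          rng_seed = 42)
  rec <- gen_background(cfg)
  ht <- attr(rec, "highthroughput_articles")
  expect_length(ht, 20L)
  # brute-force recount of records per article
  counts <- table(rec$article_id)
  big <- names(counts)[counts >= 5]
  expect_setequal(big, ht)
  expect_true(all(counts[setdiff(names(counts), ht)] <= 4))
  # simple undirected records: no self-loops, every edge covered
  expect_true(all(rec$node_a != rec$node_b))
  n_edges_expected <- round(500 * 8 / 2)
  keys <- unique(paste(pmin(rec$node_a, rec$node_b),
                       pmax(rec$node_a, rec$node_b)))
  expect_equal(length(keys), n_edges_expected)
})

test_that("plant_module reaches the requested induced density", {
  cfg <- generator_config(background_n_nodes = 200,
                          background_mean_degree = 4,
                          n_articles = 60,
                          frac_highthroughput_articles = 0.1,
                          rng_seed = 3)
  rec <- gen_background(cfg)

  # density 1.0 on 5 nodes: complete induced subgraph (10 edges)
  pm <- plant_module(rec, module_size = 5, density = 1.0, rng_seed = 11)
  mod <- pm$truth$planted_module_nodes
  keys <- unique(paste(pmin(pm$records$node_a, pm$records$node_b),
                       pmax(pm$records$node_a, pm$records$node_b)))
  pairs <- combn(sort(mod), 2)
  induced <- sum(paste(pairs[1, ], pairs[2, ]) %in% keys)
  expect_equal(induced, 10L)

  # density 0: records unchanged
  pm0 <- plant_module(rec, module_size = 6, density = 0, rng_seed = 11)
  expect_equal(nrow(pm0$records), nrow(rec))

  # density 0.9 on 8 nodes: induced edges == ceiling(0.9 * 28), brute count
  pm9 <- plant_module(rec, module_size = 8, density = 0.9, rng_seed = 7)
  mod9 <- pm9$truth$planted_module_nodes
  keys9 <- unique(paste(pmin(pm9$records$node_a, pm9$records$node_b),
                        pmax(pm9$records$node_a, pm9$records$node_b)))
  pairs9 <- combn(sort(mod9), 2)
  induced9 <- sum(paste(pairs9[1, ], pairs9[2, ]) %in% keys9)
  expect_equal(induced9, ceiling(0.9 * 28))

  # planted records survive the literature filter (low-throughput articles)
  net <- filter_articles(consolidate(pm$records))
  keysf <- paste(pmin(net$edges$node_a, net$edges$node_b),
                 pmax(net$edges$node_a, net$edges$node_b))
  expect_true(all(paste(pairs[1, ], pairs[2, ]) %in% keysf))

  expect_error(plant_module(rec, module_size = 10000, density = 1,
                            rng_seed = 1), "module_size")
})

test_that("noiseless generation reproduces planted ratios exactly", {
  cfg <- generator_config(n_proteins = 5, n_quantified = 5, n_regulated = 1,
                          n_down = 1, n_experiments = 2,
                          labeling_schedule = c("forward", "reverse"),
                          noise_cv = 0, snr_decoy_frac = 0,
                          background_n_nodes = 0, rng_seed = 9)
  truth <- single_protein_truth(0.55)
  tabs <- gen_quant_experiments(cfg, truth, rng_seed = 5)
  fwd <- tabs$EXP1
  rev <- tabs$EXP2
  p1 <- truth$regulated_proteins$protein_id

  ratio_by_pep <- function(tab, pid) {
    sub <- tab[tab$protein_id == pid, ]
    sapply(split(sub, sub$peptide_seq), function(s)
      s$intensity[s$channel == "heavy"] / s$intensity[s$channel == "light"])
  }
  # forward: treatment carries the heavy label -> heavy/light = 0.55
  expect_equal(unname(ratio_by_pep(fwd, p1)),
               rep(0.55, length(ratio_by_pep(fwd, p1))))
  # reverse: labels swap -> heavy/light = 1/0.55, light/heavy = 0.55
  expect_equal(unname(1 / ratio_by_pep(rev, p1)),
               rep(0.55, length(ratio_by_pep(rev, p1))))
  # unregulated proteins sit at 1.0 in both directions
  p2 <- truth$protein_ids[2]
  expect_equal(unname(ratio_by_pep(fwd, p2)),
               rep(1, length(ratio_by_pep(fwd, p2))))
})

test_that("pair m/z separations encode the labeled-site count and charge", {
  cfg <- generator_config(n_proteins = 30, n_quantified = 30,
                          n_regulated = 0, n_down = 0, n_experiments = 1,
                          labeling_schedule = "forward", noise_cv = 0,
                          snr_decoy_frac = 0, background_n_nodes = 0,
                          rng_seed = 2)
  truth <- plant_regulation(cfg, rng_seed = 2)
  tab <- gen_quant_experiments(cfg, truth, rng_seed = 3)[[1]]
  sp <- split(tab, tab$peptide_seq)
  for (s in sp) {
    sep <- s$mz[s$channel == "heavy"] - s$mz[s$channel == "light"]
    expect_equal(sep, 4 * s$label_sites[1] / s$charge[1])
    # the implied mass difference is one of the 2/4/8 Da pair classes
    expect_true(round(sep * s$charge[1]) %in% c(2, 4, 8))
  }
  # a 2-labeled-site peptide at charge 2 shows an 8 Da pair 4 m/z apart
  two2 <- tab[tab$label_sites == 2 & tab$charge == 2, ]
  if (nrow(two2) > 0) {
    s <- split(two2, two2$peptide_seq)[[1]]
    expect_equal(s$mz[s$channel == "heavy"] - s$mz[s$channel == "light"], 4)
  }
})

test_that("feature tables and truth survive a round trip through disk", {
  cfg <- generator_config(n_proteins = 4, n_quantified = 4, n_regulated = 1,
                          n_down = 1, n_experiments = 1,
                          labeling_schedule = "forward",
                          background_n_nodes = 0, rng_seed = 1)
  truth <- plant_regulation(cfg)
  tab <- gen_quant_experiments(cfg, truth)[[1]]
  f <- tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  expect_equal(read_feature_table(f), tab, tolerance = 1e-12)
  tf <- tempfile(fileext = ".json")
  write_truth(truth, tf)
  back <- read_truth(tf)
  expect_equal(back$regulated_proteins$protein_id,
               truth$regulated_proteins$protein_id)
  expect_equal(back$quantified_ids, truth$quantified_ids)
})
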