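# Peak-pair matching, label-swap ratio handling, protein aggregation with
# the identification-score gate, and seed selection.

fig1_features <- function(rt_gap = 10, snr = c(25, 22)) {
  data.frame(
    experiment_id = "E1", direction = "forward", protein_id = "NSF",
    peptide_seq = "LFGLLK", label_sites = 2L, charge = 2L,
    channel = c("light", "heavy"), mz = c(495.3, 499.3),
    rt_seconds = c(1000, 1000 + rt_gap), intensity = c(200, 110),
    snr = snr, id_score = 85, stringsAsFactors = FALSE)
}

test_that("an 8 Da pair at charge 2 is matched; window violations are not", {
  pairs <- match_peak_pairs(fig1_features())
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$mass_diff_da, 8)
  expect_equal(pairs$ratio_heavy_over_light, 110 / 200)

  # retention-time separation beyond 30 s
  expect_equal(nrow(match_peak_pairs(fig1_features(rt_gap = 45))), 0L)
  # signal-to-noise at or below the gate
  expect_equal(nrow(match_peak_pairs(fig1_features(snr = c(9, 22)))), 0L)
  expect_equal(nrow(match_peak_pairs(fig1_features(snr = c(10, 22)))), 0L)
  # parameter validation
  expect_error(match_peak_pairs(fig1_features(), rt_window = -1),
               "non-negative")
})

test_that("matching equals the O(n^2) brute-force oracle on random tables", {
  for (seed in 1:8) {
    tab <- random_feature_table(25, seed = seed)
    got <- match_peak_pairs(tab)
    exp <- oracle_match_pairs(tab)
    expect_equal(got[order(got$light_idx), c("light_idx", "heavy_idx")],
                 exp, ignore_attr = TRUE)
  }
})

test_that("no feature is used twice and pair count is bounded", {
  for (seed in 11:14) {
    tab <- random_feature_table(40, seed = seed)
    pairs <- match_peak_pairs(tab)
    idx <- c(pairs$light_idx, pairs$heavy_idx)
    expect_false(any(duplicated(idx)))
    expect_lte(nrow(pairs), floor(nrow(tab) / 2))
  }
})

test_that("peptide ratios express treatment/control under both labelings", {
  fwd <- data.frame(experiment_id = "E1", direction = "forward",
                    protein_id = "P1", peptide_seq = "AAK",
                    intensity_light = 200, intensity_heavy = 110,
                    stringsAsFactors = FALSE)
  expect_equal(peptide_ratio(fwd)$ratio_morphine_over_saline, 0.55)
  rev <- fwd
  rev$direction <- "reverse"
  rev$intensity_light <- 110
  rev$intensity_heavy <- 200
  expect_equal(peptide_ratio(rev)$ratio_morphine_over_saline, 0.55)
  bad <- fwd
  bad$intensity_light <- 0
  expect_error(peptide_ratio(bad), "positive")
  expect_error(peptide_ratio(fwd, direction = "sideways"), "direction")
})

test_that("a noiseless change keeps its value across forward and reverse labeling", {
  cfg <- generator_config(n_proteins = 6, n_quantified = 6, n_regulated = 1,
                          n_down = 1, n_experiments = 2,
                          labeling_schedule = c("forward", "reverse"),
                          noise_cv = 0, snr_decoy_frac = 0,
                          background_n_nodes = 0, rng_seed = 21)
  truth <- single_protein_truth(0.55, n_proteins = 6)
  tabs <- gen_quant_experiments(cfg, truth, rng_seed = 8)
  prm <- quantify_experiments(tabs)
  p1 <- truth$regulated_proteins$protein_id
  expect_equal(prm$ratios[p1, "EXP1"], 0.55, tolerance = 1e-12)
  expect_lt(abs(log(prm$ratios[p1, "EXP1"]) - log(prm$ratios[p1, "EXP2"])),
            1e-12)
})

test_that("protein aggregation averages peptides and applies the score gate", {
  pr <- data.frame(experiment_id = "E1", protein_id = "P1",
                   peptide_seq = c("A", "B", "C"),
                   ratio_morphine_over_saline = c(0.5, 0.6, 0.7),
                   stringsAsFactors = FALSE)
  feats <- data.frame(experiment_id = "E1", direction = "forward",
                      protein_id = "P1", peptide_seq = c("A", "B", "C"),
                      id_score = c(80, 75, 61), stringsAsFactors = FALSE)
  prm <- aggregate_protein_ratios(pr, feats)
  expect_equal(unname(prm$ratios["P1", "E1"]), 0.6)
  expect_equal(unname(prm$n_peptides["P1", "E1"]), 3L)

  # one peptide at 59 drops the whole protein
  feats$id_score[2] <- 59
  prm2 <- aggregate_protein_ratios(pr, feats)
  expect_false("P1" %in% rownames(prm2$ratios))
  expect_identical(prm2$dropped_proteins, "P1")
})

test_that("aggregation equals an independent groupby-mean recomputation", {
  set.seed(99)
  n <- 200
  pr <- data.frame(
    experiment_id = sample(c("E1", "E2"), n, TRUE),
    protein_id = sample(sprintf("P%02d", 1:20), n, TRUE),
    peptide_seq = sprintf("pep%03d", seq_len(n)),
    ratio_morphine_over_saline = runif(n, 0.2, 3),
    stringsAsFactors = FALSE)
  feats <- data.frame(experiment_id = pr$experiment_id,
                      direction = "forward",
                      protein_id = pr$protein_id,
                      peptide_seq = pr$peptide_seq,
                      id_score = 100, stringsAsFactors = FALSE)
  prm <- aggregate_protein_ratios(pr, feats)
  for (p in unique(pr$protein_id)) {
    for (e in unique(pr$experiment_id)) {
      sub <- pr$ratio_morphine_over_saline[pr$protein_id == p &
                                             pr$experiment_id == e]
      if (length(sub))
        expect_equal(unname(prm$ratios[p, e]), mean(sub))
      else
        expect_true(is.na(prm$ratios[p, e]))
    }
  }
})

make_prm <- function(ratios) {
  out <- list(ratios = ratios,
              n_peptides = (!is.na(ratios)) * 1L,
              experiments = colnames(ratios),
              directions = setNames(rep("forward", ncol(ratios)),
                                    colnames(ratios)),
              min_id_score = 60, dropped_proteins = character(0))
  class(out) <- "protein_ratio_matrix"
  out
}

test_that("seed selection requires consistent direction in >= 2 experiments", {
  # 10 background proteins at ratio 1, one strongly down in E1 and E3,
  # one down in E1 but up in E2 (conflict), one down only once
  ratios <- matrix(1, nrow = 13, ncol = 3,
                   dimnames = list(sprintf("P%02d", 1:13),
                                   c("E1", "E2", "E3")))
  jitter <- seq(0.95, 1.05, length.out = 10)
  ratios[1:10, ] <- matrix(rep(jitter, 3), ncol = 3)
  ratios["P11", ] <- c(0.3, 1.0, 0.35)   # consistent down twice
  ratios["P12", ] <- c(0.3, 3.0, 1.0)    # conflicting directions
  ratios["P13", ] <- c(0.3, 1.0, 1.0)    # down only once
  seeds <- select_seeds(make_prm(ratios))
  expect_identical(seeds$protein_id, "P11")
  expect_identical(seeds$direction, "down")
})

test_that("seed selection is invariant to ordering and uniform rescaling", {
  set.seed(4)
  ratios <- matrix(exp(rnorm(60, 0, 0.4)), nrow = 20, ncol = 3,
                   dimnames = list(sprintf("P%02d", 1:20),
                                   c("E1", "E2", "E3")))
  s0 <- select_seeds(make_prm(ratios))
  perm <- sample(nrow(ratios))
  s1 <- select_seeds(make_prm(ratios[perm, ]))
  expect_setequal(paste(s0$protein_id, s0$direction),
                  paste(s1$protein_id, s1$direction))
  # uniform intensity rescaling multiplies one experiment's ratios by a
  # constant; log-scale centering makes selection invariant
  scaled <- ratios
  scaled[, 2] <- scaled[, 2] * 7.3
  s2 <- select_seeds(make_prm(scaled))
  expect_setequal(paste(s0$protein_id, s0$direction),
                  paste(s2$protein_id, s2$direction))
})

test_that("degenerate ratio matrices are rejected", {
  one <- matrix(c(1, NA, 1.2, 0.9), nrow = 2,
                dimnames = list(c("P1", "P2"), c("E1", "E2")))
  expect_error(select_seeds(make_prm(one)), "fewer than 2")
})

test_that("noiseless planted regulation is recovered exactly end to end", {
  cfg <- generator_config(n_proteins = 40, n_quantified = 36,
                          n_regulated = 8, n_down = 6, n_experiments = 3,
                          labeling_schedule = c("forward", "reverse",
                                                "forward"),
                          noise_cv = 0, snr_decoy_frac = 0,
                          background_n_nodes = 0, rng_seed = 31)
  truth <- plant_regulation(cfg, rng_seed = 31)
  tabs <- gen_quant_experiments(cfg, truth, rng_seed = 32)
  prm <- quantify_experiments(tabs)
  seeds <- select_seeds(prm)
  reg <- truth$regulated_proteins
  expect_setequal(seeds$protein_id, reg$protein_id)
  expect_identical(
    seeds$direction[match(reg$protein_id, seeds$protein_id)],
    reg$direction)
})
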