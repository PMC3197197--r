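# Isotope-labeling quantification: pair light/heavy LC-MS features,
# convert pair intensities to treatment/control peptide ratios, aggregate
# to per-protein per-experiment ratios, and select the regulated seed list.

#' Match light/heavy peak pairs in one experiment's feature table
#'
#' Pairs a light-channel and a heavy-channel feature of the same peptide
#' (same `protein_id`, `peptide_seq`, `charge`, `label_sites`) when
#'
#' * the heavy m/z exceeds the light m/z and their separation equals
#'   `4 * label_sites / charge` within `mz_tol`,
#' * the implied mass difference (separation times charge) rounds to 2, 4
#'   or 8 Da,
#' * their retention times differ by at most `rt_window` seconds, and
#' * both features have signal-to-noise strictly above `snr_min`.
#'
#' Each feature joins at most one pair. When a feature could pair with
#' several candidates the pair with the smallest deviation between observed
#' and expected m/z separation wins; remaining ties are broken by smaller
#' retention-time separation, then by the row order of the input table, so
#' the output is deterministic.
#'
#' @param features Feature table of a single experiment (see
#'   [gen_quant_experiments()] for the schema).
#' @param rt_window Maximum retention-time separation in seconds.
#' @param snr_min Signal-to-noise acceptance gate (strict).
#' @param mz_tol m/z separation tolerance in Thomson.
#'
#' @return A data.frame of peak pairs: feature row indices (`light_idx`,
#'   `heavy_idx`), identification columns, `mass_diff_da`, `rt_diff`,
#'   intensities, and `ratio_heavy_over_light`.
#' @export
match_peak_pairs <- function(features, rt_window = 30, snr_min = 10,
                             mz_tol = 0.05) {
  if (rt_window < 0 || snr_min < 0 || mz_tol < 0)
    stop_param("'rt_window', 'snr_min' and 'mz_tol' must be non-negative")
  stopifnot(is.data.frame(features))
  empty <- data.frame(light_idx = integer(0), heavy_idx = integer(0),
                      experiment_id = character(0), direction = character(0),
                      protein_id = character(0), peptide_seq = character(0),
                      charge = integer(0), label_sites = integer(0),
                      mass_diff_da = numeric(0), rt_diff = numeric(0),
                      intensity_light = numeric(0),
                      intensity_heavy = numeric(0),
                      ratio_heavy_over_light = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(features) == 0L) return(empty)
  if (length(unique(features$experiment_id)) > 1L)
    stop_param("'features' must come from a single experiment")

  idx <- seq_len(nrow(features))
  li <- features$channel == "light"
  hi <- features$channel == "heavy"
  if (!any(li) || !any(hi)) return(empty)

  l <- data.frame(idx_l = idx[li],
                  protein_id = features$protein_id[li],
                  peptide_seq = features$peptide_seq[li],
                  charge = features$charge[li],
                  label_sites = features$label_sites[li],
                  mz_l = features$mz[li], rt_l = features$rt_seconds[li],
                  int_l = features$intensity[li], snr_l = features$snr[li],
                  stringsAsFactors = FALSE)
  h <- data.frame(idx_h = idx[hi],
                  protein_id = features$protein_id[hi],
                  peptide_seq = features$peptide_seq[hi],
                  charge = features$charge[hi],
                  label_sites = features$label_sites[hi],
                  mz_h = features$mz[hi], rt_h = features$rt_seconds[hi],
                  int_h = features$intensity[hi], snr_h = features$snr[hi],
                  stringsAsFactors = FALSE)
  cand <- merge(l, h,
                by = c("protein_id", "peptide_seq", "charge", "label_sites"))
  if (nrow(cand) == 0L) return(empty)

  sep <- cand$mz_h - cand$mz_l
  expected <- 4 * cand$label_sites / cand$charge
  dev <- abs(sep - expected)
  mass <- sep * cand$charge
  rtd <- abs(cand$rt_h - cand$rt_l)
  ok <- sep > 0 & dev <= mz_tol & round(mass) %in% c(2, 4, 8) &
    rtd <= rt_window & cand$snr_l > snr_min & cand$snr_h > snr_min
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  dev <- dev[ok]; mass <- mass[ok]; rtd <- rtd[ok]

  ord <- order(dev, rtd, cand$idx_l, cand$idx_h)
  used <- logical(nrow(features))
  take <- logical(nrow(cand))
  for (i in ord) {
    a <- cand$idx_l[i]; b <- cand$idx_h[i]
    if (!used[a] && !used[b]) {
      used[a] <- used[b] <- TRUE
      take[i] <- TRUE
    }
  }
  cand <- cand[take, , drop = FALSE]
  out <- data.frame(
    light_idx = cand$idx_l, heavy_idx = cand$idx_h,
    experiment_id = features$experiment_id[cand$idx_l],
    direction = features$direction[cand$idx_l],
    protein_id = cand$protein_id, peptide_seq = cand$peptide_seq,
    charge = cand$charge, label_sites = cand$label_sites,
    mass_diff_da = mass[take], rt_diff = rtd[take],
    intensity_light = cand$int_l, intensity_heavy = cand$int_h,
    ratio_heavy_over_light = cand$int_h / cand$int_l,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_id, out$peptide_seq, out$light_idx), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert peak pairs to treatment/control peptide ratios
#'
#' In a forward-labeled experiment the treatment sample carries the heavy
#' label, so the treatment/control ratio is heavy/light intensity; in a
#' reverse-labeled experiment the labels swap and the ratio is light/heavy.
#' Either way the result is expressed on the treatment/control
#' (morphine/saline) scale, so a true change keeps its direction across
#' label swaps while the raw heavy/light ratio inverts.
#'
#' @param pairs Peak-pair data.frame from [match_peak_pairs()].
#' @param direction `"forward"` or `"reverse"`; defaults to the pairs'
#'   own `direction` column.
#'
#' @return A data.frame with `experiment_id`, `protein_id`, `peptide_seq`,
#'   and `ratio_morphine_over_saline`.
#' @export
peptide_ratio <- function(pairs, direction = NULL) {
  stopifnot(is.data.frame(pairs))
  if (is.null(direction)) direction <- pairs$direction
  if (nrow(pairs) == 0L)
    return(data.frame(experiment_id = character(0),
                      protein_id = character(0),
                      peptide_seq = character(0),
                      ratio_morphine_over_saline = numeric(0),
                      stringsAsFactors = FALSE))
  direction <- rep_len(as.character(direction), nrow(pairs))
  if (!all(direction %in% c("forward", "reverse")))
    stop_param("'direction' must be 'forward' or 'reverse'")
  if (any(!is.finite(pairs$intensity_light)) ||
      any(!is.finite(pairs$intensity_heavy)) ||
      any(pairs$intensity_light <= 0) || any(pairs$intensity_heavy <= 0))
    stop_param("pair intensities must be positive")
  ratio <- ifelse(direction == "forward",
                  pairs$intensity_heavy / pairs$intensity_light,
                  pairs$intensity_light / pairs$intensity_heavy)
  data.frame(experiment_id = pairs$experiment_id,
             protein_id = pairs$protein_id,
             peptide_seq = pairs$peptide_seq,
             ratio_morphine_over_saline = ratio,
             stringsAsFactors = FALSE)
}

#' Aggregate peptide ratios to a protein ratio matrix
#'
#' Proteins with any feature below the identification-score gate (in any
#' experiment) are dropped entirely; each retained protein's per-experiment
#' ratio is the arithmetic mean of its peptide treatment/control ratios in
#' that experiment. Cells without any quantified peptide are `NA`.
#'
#' @param peptide_ratios Data.frame from [peptide_ratio()], possibly
#'   row-bound across experiments.
#' @param features The corresponding feature table(s), row-bound; supplies
#'   protein assignments, identification scores, and each experiment's
#'   labeling direction.
#' @param min_id_score Identification-score gate; a protein is kept only if
#'   every one of its features scores at least this.
#'
#' @return A `"protein_ratio_matrix"`: list with `ratios` (proteins x
#'   experiments numeric matrix), `n_peptides` (same shape),
#'   `experiments`, `directions`, `min_id_score`, `dropped_proteins`.
#' @export
aggregate_protein_ratios <- function(peptide_ratios, features,
                                     min_id_score = 60) {
  stopifnot(is.data.frame(peptide_ratios), is.data.frame(features))
  if (any(is.na(features$protein_id)) || any(features$protein_id == ""))
    stop_param("every feature must carry a protein assignment")
  if (any(is.na(peptide_ratios$protein_id)) ||
      any(peptide_ratios$protein_id == ""))
    stop_param("every peptide ratio must carry a protein assignment")
  dropped <- sort(unique(features$protein_id[features$id_score <
                                               min_id_score]))
  keep <- !(peptide_ratios$protein_id %in% dropped)
  pr <- peptide_ratios[keep, , drop = FALSE]
  experiments <- unique(features$experiment_id)
  proteins <- sort(setdiff(unique(features$protein_id), dropped))
  ratios <- matrix(NA_real_, length(proteins), length(experiments),
                   dimnames = list(proteins, experiments))
  npep <- matrix(0L, length(proteins), length(experiments),
                 dimnames = list(proteins, experiments))
  if (nrow(pr) > 0) {
    agg <- aggregate(pr$ratio_morphine_over_saline,
                     by = list(pid = pr$protein_id,
                               eid = pr$experiment_id),
                     FUN = mean)
    cnt <- aggregate(pr$ratio_morphine_over_saline,
                     by = list(pid = pr$protein_id,
                               eid = pr$experiment_id),
                     FUN = length)
    ratios[cbind(agg$pid, agg$eid)] <- agg$x
    npep[cbind(cnt$pid, cnt$eid)] <- as.integer(cnt$x)
  }
  dir_map <- unique(features[, c("experiment_id", "direction")])
  directions <- setNames(dir_map$direction, dir_map$experiment_id)[experiments]
  out <- list(ratios = ratios, n_peptides = npep, experiments = experiments,
              directions = directions, min_id_score = min_id_score,
              dropped_proteins = dropped)
  class(out) <- "protein_ratio_matrix"
  out
}

#' @export
print.protein_ratio_matrix <- function(x, ...) {
  cat(sprintf("protein ratio matrix: %d proteins x %d experiments (%d dropped by id-score gate >= %s)\n",
              nrow(x$ratios), ncol(x$ratios), length(x$dropped_proteins),
              format(x$min_id_score)))
  invisible(x)
}

#' Select the regulated seed list from a protein ratio matrix
#'
#' Per experiment, the mean and standard deviation of the natural-log
#' ratios are computed across all quantified proteins. A protein "changes"
#' in an experiment when its log-ratio lies at least `sd_multiple`
#' standard deviations from that experiment's mean, with direction given by
#' the sign of the deviation. A protein is selected when it changes in at
#' least `min_consistent` experiments and all of its threshold-passing
#' changes share one direction; proteins with threshold-passing changes in
#' both directions are rejected. The log scale makes up- and
#' down-regulation symmetric (2x and 0.5x are equidistant from no change).
#'
#' @param matrix A `"protein_ratio_matrix"` from
#'   [aggregate_protein_ratios()].
#' @param sd_multiple Threshold in per-experiment standard deviations.
#' @param min_consistent Minimum number of same-direction changes.
#'
#' @return A `"seed_list"` data.frame with columns `protein_id` and
#'   `direction` (`"up"`/`"down"`), carrying the thresholds as attributes.
#' @export
select_seeds <- function(matrix, sd_multiple = 0.5, min_consistent = 2L) {
  stopifnot(inherits(matrix, "protein_ratio_matrix"))
  sd_multiple <- check_number(sd_multiple, "sd_multiple", 0)
  min_consistent <- check_count(min_consistent, "min_consistent", 1L)
  lr <- log(matrix$ratios)
  if (nrow(lr) == 0L) stop_param("'matrix' is empty")
  n_obs <- colSums(!is.na(lr))
  if (any(n_obs < 2L))
    stop_param(sprintf(
      "experiment(s) %s have fewer than 2 quantified proteins (SD undefined)",
      paste(colnames(lr)[n_obs < 2L], collapse = ", ")))
  mu <- colMeans(lr, na.rm = TRUE)
  sdv <- apply(lr, 2L, sd, na.rm = TRUE)
  dev <- sweep(lr, 2L, mu)
  thr <- sweep(abs(dev), 2L, sd_multiple * sdv, `>=`)
  chg <- sign(dev) * (thr & !is.na(dev))
  up <- rowSums(chg == 1, na.rm = TRUE)
  dn <- rowSums(chg == -1, na.rm = TRUE)
  sel_up <- up >= min_consistent & dn == 0L
  sel_dn <- dn >= min_consistent & up == 0L
  out <- data.frame(
    protein_id = rownames(lr)[sel_up | sel_dn],
    direction = ifelse(sel_up[sel_up | sel_dn], "up", "down"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sd_multiple") <- sd_multiple
  attr(out, "min_consistent") <- min_consistent
  class(out) <- c("seed_list", "data.frame")
  out
}

#' Quantify a set of feature tables end to end
#'
#' Convenience wrapper: matches peak pairs and computes peptide ratios per
#' experiment, then aggregates everything into one protein ratio matrix.
#'
#' @param tables List of per-experiment feature tables.
#' @param rt_window,snr_min,mz_tol Passed to [match_peak_pairs()].
#' @param min_id_score Passed to [aggregate_protein_ratios()].
#' @return A `"protein_ratio_matrix"`.
#' @export
quantify_experiments <- function(tables, rt_window = 30, snr_min = 10,
                                 mz_tol = 0.05, min_id_score = 60) {
  stopifnot(is.list(tables), length(tables) > 0)
  ratios <- lapply(tables, function(tab) {
    peptide_ratio(match_peak_pairs(tab, rt_window = rt_window,
                                   snr_min = snr_min, mz_tol = mz_tol))
  })
  aggregate_protein_ratios(do.call(rbind, c(ratios, make.row.names = FALSE)),
                           do.call(rbind, c(tables, make.row.names = FALSE)),
                           min_id_score = min_id_score)
}

#' Write a protein ratio matrix with its threshold sidecar
#'
#' Writes a TSV (`protein_id`, one ratio column per experiment,
#' `n_peptides` total) and a JSON sidecar recording the thresholds used.
#'
#' @param matrix A `"protein_ratio_matrix"`.
#' @param path TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "protein_ratio_matrix"))
  df <- data.frame(protein_id = rownames(matrix$ratios),
                   matrix$ratios,
                   n_peptides = rowSums(matrix$n_peptides),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(min_id_score = matrix$min_id_score,
         experiments = matrix$experiments,
         directions = as.list(matrix$directions),
         dropped_proteins = matrix$dropped_proteins),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a seed list with its threshold sidecar
#'
#' @param seeds A `"seed_list"` from [select_seeds()].
#' @param path TSV path; thresholds go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_seed_list <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_list"))
  write.table(as.data.frame(seeds), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(
    list(sd_multiple = attr(seeds, "sd_multiple"),
         min_consistent = attr(seeds, "min_consistent"),
         n_seeds = nrow(seeds)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
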