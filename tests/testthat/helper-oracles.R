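# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms (exhaustive
# enumeration, O(n^2) scans) and share no code with the package.

# --- peak-pair matching: O(n^2) predicate check + greedy assignment -------
oracle_match_pairs <- function(features, rt_window = 30, snr_min = 10,
                               mz_tol = 0.05) {
  n <- nrow(features)
  ch <- features$channel; prot <- features$protein_id
  pep <- features$peptide_seq; chg <- features$charge
  sites <- features$label_sites; mz <- features$mz
  rt <- features$rt_seconds; snr <- features$snr
  cand <- list()
  for (i in seq_len(n)) {
    if (ch[i] != "light") next
    for (j in seq_len(n)) {
      if (ch[j] != "heavy") next
      if (prot[i] != prot[j] || pep[i] != pep[j]) next
      if (chg[i] != chg[j] || sites[i] != sites[j]) next
      sep <- mz[j] - mz[i]
      if (sep <= 0) next
      expected <- 4 * sites[i] / chg[i]
      if (abs(sep - expected) > mz_tol) next
      if (!(round(sep * chg[i]) %in% c(2, 4, 8))) next
      if (abs(rt[j] - rt[i]) > rt_window) next
      if (snr[i] <= snr_min || snr[j] <= snr_min) next
      cand[[length(cand) + 1L]] <- data.frame(
        light_idx = i, heavy_idx = j,
        dev = abs(sep - expected),
        rtd = abs(rt[j] - rt[i]))
    }
  }
  if (!length(cand))
    return(data.frame(light_idx = integer(0), heavy_idx = integer(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dev, cand$rtd, cand$light_idx, cand$heavy_idx), ]
  used <- logical(n)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- cand$light_idx[r]; b <- cand$heavy_idx[r]
    if (!used[a] && !used[b]) { used[a] <- used[b] <- TRUE; keep[r] <- TRUE }
  }
  out <- cand[keep, c("light_idx", "heavy_idx")]
  out <- out[order(out$light_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- record consolidation: set-based dedupe -------------------------------
oracle_consolidate_counts <- function(records) {
  a <- toupper(trimws(records$node_a))
  b <- toupper(trimws(records$node_b))
  keep <- a != b
  keys <- unique(paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]),
                       sep = "::"))
  nodes <- unique(c(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
  list(n_nodes = length(nodes), n_edges = length(keys))
}

# --- expansion: exhaustive simple-path enumeration via igraph -------------
oracle_expand <- function(seed_ids, g, max_links = 3) {
  s_in <- intersect(seed_ids, igraph::V(g)$name)
  edge_set <- character(0)
  inter_set <- character(0)
  for (s in s_in) {
    targets <- setdiff(s_in, s)
    if (!length(targets)) next
    paths <- igraph::all_simple_paths(g, from = s, to = targets,
                                      cutoff = max_links)
    for (p in paths) {
      nm <- names(p)
      interior <- nm[-c(1, length(nm))]
      if (any(interior %in% s_in)) next
      inter_set <- c(inter_set, interior)
      for (e in seq_len(length(nm) - 1L))
        edge_set <- c(edge_set, paste(pmin(nm[e], nm[e + 1L]),
                                      pmax(nm[e], nm[e + 1L]),
                                      sep = "::"))
    }
  }
  list(edges = sort(unique(edge_set)),
       intermediates = sort(unique(inter_set)))
}

# --- pooled two-proportion z, coded independently -------------------------
oracle_ztest <- function(s, d, S, N) {
  p1 <- s / d
  p2 <- S / N
  if (p1 == p2) return(0)
  phat <- (s + S) / (d + N)
  se <- sqrt(phat * (1 - phat) * (1 / d + 1 / N))
  if (se == 0) return(0)
  (p1 - p2) / se
}

# --- average clustering: explicit triangle counting -----------------------
oracle_avg_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    d <- length(nb)
    if (d < 2) { cc[v] <- 0; next }
    tri <- 0
    for (x in seq_len(d - 1)) {
      for (y in (x + 1):d) {
        if (A[nb[x], nb[y]] > 0) tri <- tri + 1
      }
    }
    cc[v] <- tri / (d * (d - 1) / 2)
  }
  mean(cc)
}

# --- k-clique enumeration: exhaustive subset check ------------------------
oracle_k_cliques <- function(g, k) {
  nodes <- sort(igraph::V(g)$name)
  if (length(nodes) < k) return(list())
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  rownames(A) <- colnames(A) <- igraph::V(g)$name
  combs <- combn(nodes, k)
  pairs <- combn(k, 2)
  complete <- rep(TRUE, ncol(combs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    complete <- complete & (A[cbind(combs[i, ], combs[j, ])] > 0)
  }
  lapply(which(complete), function(c) combs[, c])
}

# --- clique percolation: exhaustive k-subsets + (k-1)-subset grouping -----
oracle_percolation <- function(g, k) {
  cl <- oracle_k_cliques(g, k)
  if (!length(cl)) return(list())
  n <- length(cl)
  parent <- seq_len(n)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # two distinct k-cliques are adjacent iff they share a (k-1)-subset
  key_map <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    for (drop in seq_len(k)) {
      key <- paste(cl[[i]][-drop], collapse = "::")
      prev <- key_map[[key]]
      if (is.null(prev)) {
        key_map[[key]] <- i
      } else {
        ri <- findr(i); rj <- findr(prev)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), findr, integer(1))
  comps <- split(seq_len(n), roots)
  clusters <- lapply(comps, function(ids)
    sort(unique(unlist(cl[ids]))))
  unname(clusters)
}

# canonical form for comparing families of clusters
canonical_clusters <- function(clusters) {
  cl <- lapply(clusters, sort)
  keys <- vapply(cl, paste, character(1), collapse = "::")
  unname(cl[order(keys)])
}

# --- fixture builders -----------------------------------------------------
make_er_graph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p)
}

named_er_graph <- function(n, p, seed) {
  g <- make_er_graph(n, p, seed)
  igraph::set_vertex_attr(g, "name",
                          value = sprintf("N%03d", seq_len(n)))
}

# a background_network built directly from an edge data.frame
make_net <- function(edges, articles = NULL) {
  records <- data.frame(node_a = edges[, 1], node_b = edges[, 2],
                        dataset = "test",
                        article_id = if (is.null(articles)) "a1"
                                     else articles,
                        stringsAsFactors = FALSE)
  consolidate(records)
}

# random single-experiment feature table exercising the pair matcher:
# intact pairs, RT/SNR/mz violations, shuffled row order
random_feature_table <- function(n_peptides, seed) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_peptides)) {
    sites <- sample(1:2, 1)
    charge <- sample(1:2, 1)
    mz <- runif(1, 300, 1200)
    rt <- runif(1, 100, 3000)
    sep <- 4 * sites / charge
    kind <- sample(c("good", "bad_rt", "bad_snr", "bad_mz", "orphan",
                     "dup"), 1,
                   prob = c(0.4, 0.15, 0.15, 0.1, 0.1, 0.1))
    rt_h <- rt + switch(kind, bad_rt = runif(1, 35, 80),
                        runif(1, -25, 25))
    snr_l <- if (kind == "bad_snr") runif(1, 1, 9) else runif(1, 11, 60)
    mz_h <- mz + sep + if (kind == "bad_mz") runif(1, 0.2, 0.5) else 0
    pep <- sprintf("PEP%02d%s", i, if (sites == 2) "K" else "R")
    prot <- sprintf("P%02d", ceiling(i / 2))
    rows[[length(rows) + 1L]] <- data.frame(
      experiment_id = "E1", direction = "forward", protein_id = prot,
      peptide_seq = pep, label_sites = sites, charge = charge,
      channel = "light", mz = mz, rt_seconds = rt,
      intensity = runif(1, 1e4, 1e6), snr = snr_l,
      id_score = runif(1, 60, 120), stringsAsFactors = FALSE)
    if (kind != "orphan") {
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = "E1", direction = "forward", protein_id = prot,
        peptide_seq = pep, label_sites = sites, charge = charge,
        channel = "heavy", mz = mz_h, rt_seconds = rt_h,
        intensity = runif(1, 1e4, 1e6), snr = runif(1, 11, 60),
        id_score = runif(1, 60, 120), stringsAsFactors = FALSE)
    }
    if (kind == "dup") {
      # a second in-tolerance heavy candidate forces the deterministic
      # best-match tie-break
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = "E1", direction = "forward", protein_id = prot,
        peptide_seq = pep, label_sites = sites, charge = charge,
        channel = "heavy", mz = mz + sep + runif(1, -0.04, 0.04),
        rt_seconds = rt + runif(1, -25, 25),
        intensity = runif(1, 1e4, 1e6), snr = runif(1, 11, 60),
        id_score = runif(1, 60, 120), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[sample(nrow(tab)), ]
  rownames(tab) <- NULL
  tab
}

# planted-truth object with a single regulated protein at a given
# fold-change, for noiseless ratio checks
single_protein_truth <- function(fc, n_proteins = 5) {
  ids <- sprintf("PROT%03d", seq_len(n_proteins))
  truth <- list(
    regulated_proteins = data.frame(protein_id = ids[1],
                                    direction = if (fc < 1) "down" else "up",
                                    log2_fc = log2(fc), fold_change = fc,
                                    stringsAsFactors = FALSE),
    protein_ids = ids, quantified_ids = ids,
    planted_module_nodes = character(0), rng_seed = 1L)
  class(truth) <- "planted_truth"
  truth
}
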