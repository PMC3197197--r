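# Enrichment of seed-list neighbors around intermediates: pooled
# two-proportion z-test comparing a node's fraction of seed neighbors with
# the network-wide seed fraction, plus the score tiers used to call
# significant and highly significant interactors.

#' Pooled two-proportion z statistic
#'
#' Compares the proportion `s/d` (a node's seed neighbors among its
#' interactions) with `S/N` (seed proteins among all network nodes) using
#' the pooled standard error:
#' `z = (s/d - S/N) / sqrt(p(1-p)(1/d + 1/N))` with
#' `p = (s + S)/(d + N)`. When the pooled variance term is zero the score
#' is reported as 0.
#'
#' @param s Successes in the first sample (seed neighbors).
#' @param d First sample size (node degree).
#' @param S Successes in the second sample (seed nodes in the network).
#' @param N Second sample size (network node count).
#' @return Numeric z score(s); vectorized over its arguments.
#' @export
proportions_ztest <- function(s, d, S, N) {
  if (any(d <= 0) || any(N <= 0))
    stop_param("'d' and 'N' must be positive")
  if (any(s < 0) || any(s > d) || any(S < 0) || any(S > N))
    stop_param("need 0 <= s <= d and 0 <= S <= N")
  p <- (s + S) / (d + N)
  v <- p * (1 - p) * (1 / d + 1 / N)
  z <- ifelse(v > 0, ((s / d) - (S / N)) / sqrt(v), 0)
  # equal proportions give exactly 0 regardless of rounding
  ifelse(s / d == S / N, 0, z)
}

#' Classify an enrichment score into significance tiers
#'
#' Strict thresholds: `z > high_threshold` is `"highly_significant"`,
#' `sig_threshold < z <= high_threshold` is `"significant"`, anything else
#' `"none"` (so z = 2 is `"none"` and z = 3 is `"significant"`).
#'
#' @param z Numeric score(s).
#' @param sig_threshold Lower (strict) threshold for significance.
#' @param high_threshold Lower (strict) threshold for high significance.
#' @return Character vector of tiers.
#' @export
classify_score <- function(z, sig_threshold = 2, high_threshold = 3) {
  if (!(sig_threshold <= high_threshold))
    stop_param("'sig_threshold' must not exceed 'high_threshold'")
  ifelse(z > high_threshold, "highly_significant",
         ifelse(z > sig_threshold, "significant", "none"))
}

#' Enrichment score of one background node for seed-list neighbors
#'
#' @param node A node symbol present in `net`.
#' @param seeds A `"seed_list"` or character vector of seed symbols.
#' @param net A `"background_network"`.
#' @param sig_threshold,high_threshold Tier thresholds (strict).
#'
#' @return A one-row data.frame with `node`, `degree_background`,
#'   `seed_neighbors`, `z`, `tier`.
#' @export
intermediate_zscore <- function(node, seeds, net, sig_threshold = 2,
                                high_threshold = 3) {
  stopifnot(inherits(net, "background_network"))
  if (inherits(seeds, "seed_list") || is.data.frame(seeds))
    seeds <- seeds$protein_id
  seeds <- unique(toupper(trimws(as.character(seeds))))
  node <- toupper(trimws(node))
  if (!(node %in% net$nodes))
    stop_param(sprintf("node '%s' is not in the background network", node))
  s_in <- intersect(seeds, net$nodes)
  nb <- c(net$edges$node_b[net$edges$node_a == node],
          net$edges$node_a[net$edges$node_b == node])
  d <- length(nb)
  if (d == 0L)
    stop_param(sprintf("node '%s' has degree 0; score undefined", node))
  s <- sum(nb %in% s_in)
  z <- proportions_ztest(s, d, length(s_in), length(net$nodes))
  data.frame(node = node, degree_background = d, seed_neighbors = s,
             z = z,
             tier = classify_score(z, sig_threshold, high_threshold),
             stringsAsFactors = FALSE)
}

#' Enrichment table for a set of nodes
#'
#' Scores every requested node (typically the subnetwork's intermediates)
#' against the background and sorts by decreasing z, ties broken
#' lexicographically by node symbol.
#'
#' @param nodes Character vector of node symbols (e.g.
#'   `subnetwork$intermediate_nodes`).
#' @param seeds A `"seed_list"` or character vector.
#' @param net A `"background_network"`.
#' @param sig_threshold,high_threshold Tier thresholds (strict).
#'
#' @return Data.frame with one row per node: `node`,
#'   `degree_background`, `seed_neighbors`, `z`, `tier`.
#' @export
enrichment_table <- function(nodes, seeds, net, sig_threshold = 2,
                             high_threshold = 3) {
  stopifnot(inherits(net, "background_network"))
  if (inherits(seeds, "seed_list") || is.data.frame(seeds))
    seeds <- seeds$protein_id
  seeds <- unique(toupper(trimws(as.character(seeds))))
  nodes <- unique(toupper(trimws(as.character(nodes))))
  if (length(nodes) == 0L)
    return(data.frame(node = character(0), degree_background = integer(0),
                      seed_neighbors = integer(0), z = numeric(0),
                      tier = character(0), stringsAsFactors = FALSE))
  missing <- setdiff(nodes, net$nodes)
  if (length(missing))
    stop_param(sprintf("node(s) not in background: %s",
                       paste(utils::head(missing, 5L), collapse = ", ")))
  s_in <- intersect(seeds, net$nodes)
  # degree and seed-neighbor counts in one pass over the edge list
  ea <- net$edges$node_a; eb <- net$edges$node_b
  endpoints <- c(ea, eb)
  others <- c(eb, ea)
  deg <- table(factor(endpoints, levels = nodes))
  snb <- table(factor(endpoints[others %in% s_in], levels = nodes))
  d <- as.integer(deg[nodes])
  s <- as.integer(snb[nodes])
  if (any(d == 0L))
    stop_param(sprintf("node(s) with degree 0: %s",
                       paste(utils::head(nodes[d == 0L], 5L),
                             collapse = ", ")))
  z <- proportions_ztest(s, d, length(s_in), length(net$nodes))
  out <- data.frame(node = nodes, degree_background = d, seed_neighbors = s,
                    z = z,
                    tier = classify_score(z, sig_threshold, high_threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count enrichment tiers
#'
#' @param table An enrichment table from [enrichment_table()].
#' @return List with `n_significant` (z above the significance threshold,
#'   including highly significant nodes) and `n_highly_significant`.
#' @export
tier_counts <- function(table) {
  list(n_significant = sum(table$tier %in% c("significant",
                                             "highly_significant")),
       n_highly_significant = sum(table$tier == "highly_significant"))
}
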