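# Overlapping community detection by k-clique percolation: a k-clique is a
# complete subgraph on k nodes, two k-cliques are adjacent when they share
# k-1 nodes, and a percolation cluster is the node union of a maximal set
# of k-cliques connected through chains of adjacent k-cliques. Nodes may
# belong to several clusters.

#' Enumerate all k-cliques of a graph
#'
#' @param graph An undirected simple `igraph` graph.
#' @param k Clique size, at least 2.
#' @return A list of sorted character vectors, one per complete k-node
#'   subgraph, in deterministic order.
#' @export
enumerate_k_cliques <- function(graph, k) {
  stopifnot(igraph::is_igraph(graph))
  k <- check_count(k, "k", 2L)
  cl <- igraph::cliques(graph, min = k, max = k)
  out <- lapply(cl, function(v) sort(names(v)))
  keys <- vapply(out, paste, character(1), collapse = "|")
  out[order(keys)]
}

#' Locate k-clique percolation clusters
#'
#' Implemented through maximal cliques: every maximal clique of size `>= k`
#' is a fully percolated unit (any two of its k-cliques are connected by
#' single-node swaps), and two such maximal cliques host adjacent k-cliques
#' exactly when they overlap in at least `k - 1` nodes. Connected
#' components of that overlap relation therefore yield the same clusters as
#' exhaustively percolating all k-cliques, at polynomial bookkeeping cost.
#'
#' @param graph An undirected simple `igraph` graph.
#' @param k Clique size, at least 2 (with `k = 2` the clusters are the
#'   connected components with at least one edge).
#'
#' @return A `"cluster_set"`: list with `k` and `clusters`, a list of
#'   sorted node-name vectors ordered by decreasing size then by first
#'   member.
#' @export
percolation_clusters <- function(graph, k) {
  stopifnot(igraph::is_igraph(graph))
  k <- check_count(k, "k", 2L)
  mc <- igraph::max_cliques(graph, min = k)
  mc <- lapply(mc, function(v) sort(names(v)))
  n <- length(mc)
  if (n == 0L)
    return(structure(list(k = k, clusters = list()), class = "cluster_set"))

  # union-find with path compression over maximal-clique ids
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  sizes <- lengths(mc)
  # Candidate pairs via shared membership: cliques sharing >= k-1 nodes
  # share at least one node, so only pairs meeting in some node's clique
  # list need checking.
  node_to_cliques <- split(rep(seq_len(n), sizes),
                           unlist(mc, use.names = FALSE))
  checked <- new.env(hash = TRUE)
  for (ids in node_to_cliques) {
    ids <- unique(ids)
    if (length(ids) < 2L) next
    for (ii in seq_len(length(ids) - 1L)) {
      for (jj in (ii + 1L):length(ids)) {
        i <- ids[ii]; j <- ids[jj]
        key <- paste(min(i, j), max(i, j))
        if (!is.null(checked[[key]])) next
        checked[[key]] <- TRUE
        if (find(i) == find(j)) next
        if (length(intersect(mc[[i]], mc[[j]])) >= k - 1L)
          parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  clusters <- lapply(comps, function(ids)
    sort(unique(unlist(mc[ids], use.names = FALSE))))
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1), 1L))
  structure(list(k = k, clusters = unname(clusters[ord])),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d cluster(s) with k = %d\n", length(x$clusters), x$k))
  for (i in seq_along(x$clusters))
    cat(sprintf("  [%d] (%d nodes) %s\n", i, length(x$clusters[[i]]),
                paste(x$clusters[[i]], collapse = ", ")))
  invisible(x)
}

#' Summarize cluster sets across k values
#'
#' @param sets A list of `"cluster_set"` objects (one per k).
#' @return A list with `table` (data.frame: `k`, `cluster_id`, `size`,
#'   `members`), `counts` (named per-k cluster counts), `summary_line`
#'   (human-readable count summary), and `overlap` (per-k matrices of
#'   shared node counts between clusters).
#' @export
cluster_report <- function(sets) {
  if (inherits(sets, "cluster_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "cluster_set")))
  rows <- list()
  counts <- integer(0)
  overlap <- list()
  for (cs in sets) {
    counts[as.character(cs$k)] <- length(cs$clusters)
    if (length(cs$clusters)) {
      rows[[length(rows) + 1L]] <- data.frame(
        k = cs$k,
        cluster_id = seq_along(cs$clusters),
        size = lengths(cs$clusters),
        members = vapply(cs$clusters, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
      ov <- outer(seq_along(cs$clusters), seq_along(cs$clusters),
                  Vectorize(function(i, j)
                    length(intersect(cs$clusters[[i]], cs$clusters[[j]]))))
      overlap[[as.character(cs$k)]] <- ov
    } else {
      overlap[[as.character(cs$k)]] <-
        matrix(integer(0), nrow = 0, ncol = 0)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(k = integer(0), cluster_id = integer(0),
                         size = integer(0), members = character(0),
                         stringsAsFactors = FALSE)
  ks <- sort(as.integer(names(counts)), decreasing = TRUE)
  line <- paste(sprintf("%d clusters with k = %d", counts[as.character(ks)],
                        ks), collapse = " and ")
  list(table = tab, counts = counts, summary_line = line, overlap = overlap)
}

#' Write clusters as CFinder-like text plus a JSON summary
#'
#' One line per cluster: `k<TAB>cluster_id<TAB>member,member,...`.
#'
#' @param sets A list of `"cluster_set"` objects.
#' @param path Output TSV path; the summary goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(sets, path) {
  rep <- cluster_report(sets)
  write.table(rep$table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(counts = as.list(rep$counts),
                            summary = rep$summary_line),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
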