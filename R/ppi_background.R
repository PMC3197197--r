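# Background PPI network: consolidate provenance-annotated interaction
# records into one simple undirected graph and filter out interactions
# whose only literature support comes from high-throughput articles.

#' Consolidate interaction records into a background network
#'
#' Gene symbols are upper-cased and whitespace-trimmed, `(A,B)` and
#' `(B,A)` records are merged into one undirected edge, self-loops are
#' dropped, and every retained edge keeps the union of its supporting
#' article identifiers and source datasets. The result is order
#' independent: any permutation of the input records yields the same
#' network.
#'
#' @param records Data.frame with columns `node_a`, `node_b`, `dataset`,
#'   `article_id`.
#'
#' @return A `"background_network"`: list with `nodes` (sorted symbols),
#'   `edges` (data.frame `node_a` < `node_b`), `articles` and `datasets`
#'   (per-edge lists of supporting identifiers).
#' @export
consolidate <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("node_a", "node_b", "article_id")
  if (!all(need %in% names(records)))
    stop_param("records need columns node_a, node_b, article_id")
  if (!("dataset" %in% names(records)))
    records$dataset <- "unknown"
  a <- toupper(trimws(as.character(records$node_a)))
  b <- toupper(trimws(as.character(records$node_b)))
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad))
    stop_param(sprintf("malformed record(s) with empty symbols at line(s) %s",
                       paste(utils::head(bad, 5L), collapse = ", ")))
  keep <- a != b
  a2 <- pmin(a[keep], b[keep])
  b2 <- pmax(a[keep], b[keep])
  art <- as.character(records$article_id)[keep]
  ds <- as.character(records$dataset)[keep]
  key <- paste(a2, b2, sep = "\r")
  ord <- order(key)
  key <- key[ord]; a2 <- a2[ord]; b2 <- b2[ord]
  art <- art[ord]; ds <- ds[ord]
  first <- !duplicated(key)
  ukey <- key[first]
  f <- factor(key, levels = ukey)
  articles <- lapply(split(art, f), function(x) sort(unique(x)))
  datasets <- lapply(split(ds, f), function(x) sort(unique(x)))
  edges <- data.frame(node_a = a2[first], node_b = b2[first],
                      stringsAsFactors = FALSE)
  ord2 <- order(edges$node_a, edges$node_b)
  net <- list(nodes = sort(unique(c(edges$node_a, edges$node_b))),
              edges = edges[ord2, , drop = FALSE],
              articles = unname(articles[ord2]),
              datasets = unname(datasets[ord2]))
  rownames(net$edges) <- NULL
  class(net) <- "background_network"
  net
}

#' Filter out interactions supported only by high-throughput articles
#'
#' An article is flagged high-throughput when it supports strictly more
#' than `max_per_article` edges of the network (the default 4 flags
#' articles providing five or more interactions). An edge is removed if
#' and only if *all* of its supporting articles are high-throughput; an
#' interaction with any small-scale literature evidence is kept. Nodes
#' left without edges are removed. The operation is idempotent.
#'
#' @param net A `"background_network"` from [consolidate()].
#' @param max_per_article Largest per-article edge count that still counts
#'   as low-throughput.
#'
#' @return The filtered `"background_network"`, with attributes
#'   `excluded_articles` (the high-throughput flags) and
#'   `n_edges_removed`.
#' @export
filter_articles <- function(net, max_per_article = 4L) {
  stopifnot(inherits(net, "background_network"))
  max_per_article <- check_count(max_per_article, "max_per_article", 0L)
  counts <- table(unlist(net$articles))
  ht <- names(counts)[counts >= max_per_article + 1L]
  keep <- vapply(net$articles, function(a) any(!(a %in% ht)), logical(1))
  if (length(keep) == 0L) keep <- logical(0)
  out <- list(nodes = sort(unique(c(net$edges$node_a[keep],
                                    net$edges$node_b[keep]))),
              edges = net$edges[keep, , drop = FALSE],
              articles = net$articles[keep],
              datasets = net$datasets[keep])
  rownames(out$edges) <- NULL
  class(out) <- "background_network"
  attr(out, "excluded_articles") <- sort(ht)
  attr(out, "n_edges_removed") <- sum(!keep)
  out
}

#' Number of edges of a background network
#' @param net A `"background_network"`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @export
print.background_network <- function(x, ...) {
  cat(sprintf("background network: %d nodes, %d links\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a background network or subnetwork to an igraph graph
#'
#' @param x A `"background_network"` or `"subnetwork"`.
#' @return An undirected simple `igraph` graph.
#' @export
as_igraph <- function(x) {
  UseMethod("as_igraph")
}

#' @export
as_igraph.background_network <- function(x) {
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = data.frame(name = x$nodes))
}

#' @export
as_igraph.subnetwork <- function(x) {
  nodes <- c(x$seed_nodes, x$intermediate_nodes)
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = data.frame(name = sort(nodes)))
}

#' Write a network as SIF and annotated TSV edge list
#'
#' The SIF format is one `A pp B` line per edge; the TSV adds the
#' supporting article identifiers (pipe-separated). A JSON summary (node
#' count, link count, excluded articles if any) goes to
#' `<path_prefix>_summary.json`.
#'
#' @param net A `"background_network"`.
#' @param path_prefix Output path prefix.
#' @return `path_prefix`, invisibly.
#' @export
write_network <- function(net, path_prefix) {
  stopifnot(inherits(net, "background_network"))
  sif <- sprintf("%s\tpp\t%s", net$edges$node_a, net$edges$node_b)
  writeLines(sif, paste0(path_prefix, ".sif"))
  tsv <- data.frame(node_a = net$edges$node_a, node_b = net$edges$node_b,
                    articles = vapply(net$articles, paste, character(1),
                                      collapse = "|"),
                    datasets = vapply(net$datasets, paste, character(1),
                                      collapse = "|"),
                    stringsAsFactors = FALSE)
  write.table(tsv, paste0(path_prefix, "_edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  excluded <- attr(net, "excluded_articles")
  jsonlite::write_json(
    list(n_nodes = length(net$nodes), n_links = nrow(net$edges),
         n_articles_excluded = if (is.null(excluded)) 0L
                               else length(excluded)),
    paste0(path_prefix, "_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path_prefix)
}
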