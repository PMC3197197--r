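# Seed-network expansion: connect seed proteins through at most two
# non-seed intermediates from the filtered background (paths of up to
# three links whose interior nodes are all non-seed).

#' Expand a seed list into a subnetwork over the background
#'
#' For every unordered pair of seed proteins present in the background,
#' every simple path of at most `max_intermediates + 1` links whose
#' interior nodes are all non-seed is enumerated. Interior nodes become
#' intermediates; all edges on such paths, plus direct seed-seed edges,
#' form the subnetwork. Paths running through another seed are not counted
#' as single paths (each seed-to-seed segment stands on its own), and an
#' intermediate is retained if it appears on *any* qualifying path, not
#' only on shortest ones. Seeds absent from the background are reported in
#' the `unmapped_seeds` field.
#'
#' @param seeds A `"seed_list"` (or character vector of protein symbols).
#' @param net A `"background_network"`.
#' @param max_intermediates Maximum interior nodes per connecting path
#'   (0, 1 or 2).
#'
#' @return A `"subnetwork"`: list with `seed_nodes` (seeds incident to at
#'   least one subnetwork edge), `intermediate_nodes`, `edges`
#'   (data.frame), `all_seeds` (seeds found in the background), and
#'   `unmapped_seeds`.
#' @export
expand_subnetwork <- function(seeds, net, max_intermediates = 2L) {
  stopifnot(inherits(net, "background_network"))
  max_intermediates <- check_count(max_intermediates, "max_intermediates", 0L)
  if (max_intermediates > 2L)
    stop_param("'max_intermediates' larger than 2 is not supported")
  if (length(net$nodes) == 0L || nrow(net$edges) == 0L)
    stop_param("background network is empty")
  if (inherits(seeds, "seed_list") || is.data.frame(seeds))
    seeds <- seeds$protein_id
  seeds <- unique(toupper(trimws(as.character(seeds))))
  if (length(seeds) == 0L) stop_param("'seeds' is empty")
  s_in <- intersect(seeds, net$nodes)
  unmapped <- sort(setdiff(seeds, net$nodes))

  ea <- net$edges$node_a
  eb <- net$edges$node_b
  a_seed <- ea %in% s_in
  b_seed <- eb %in% s_in

  keys <- character(0)
  intermediates <- character(0)

  # Direct seed-seed links (paths of one link).
  direct <- a_seed & b_seed
  keys <- edge_key(ea[direct], eb[direct])

  if (max_intermediates >= 1L && length(s_in) >= 2L) {
    # Seed neighbors of every non-seed node, from one pass over the edges.
    mixed_ab <- a_seed & !b_seed   # seed -- nonseed
    mixed_ba <- !a_seed & b_seed   # nonseed -- seed
    nonseed <- c(eb[mixed_ab], ea[mixed_ba])
    seednb <- c(ea[mixed_ab], eb[mixed_ba])
    seed_nb <- split(seednb, nonseed)

    # One intermediate: any non-seed node adjacent to >= 2 distinct seeds;
    # every edge from it to one of those seeds lies on a qualifying path.
    hubs <- names(seed_nb)[vapply(seed_nb, function(s)
      length(unique(s)) >= 2L, logical(1))]
    if (length(hubs)) {
      intermediates <- c(intermediates, hubs)
      for (x in hubs)
        keys <- c(keys, edge_key(rep(x, length(seed_nb[[x]])), seed_nb[[x]]))
    }

    if (max_intermediates >= 2L) {
      # Two intermediates: a non-seed edge (x, y) with seeds s1 ~ x and
      # s2 ~ y, s1 != s2, realizes s1-x-y-s2. The edge x-s1 qualifies
      # unless y's only seed neighbor is s1 itself (and symmetrically).
      both_non <- !a_seed & !b_seed
      xs <- ea[both_non]
      ys <- eb[both_non]
      sx <- seed_nb[xs]
      sy <- seed_nb[ys]
      has_x <- !vapply(sx, is.null, logical(1))
      has_y <- !vapply(sy, is.null, logical(1))
      cand <- which(has_x & has_y)
      acc_keys <- vector("list", length(cand))
      acc_int <- vector("list", length(cand))
      for (j in seq_along(cand)) {
        i <- cand[j]
        s1 <- unique(sx[[i]])
        s2 <- unique(sy[[i]])
        if (length(s1) == 1L && length(s2) == 1L && s1 == s2)
          next                       # same single seed at both ends
        x <- xs[i]; y <- ys[i]
        ok1 <- if (length(s2) > 1L) s1 else setdiff(s1, s2)
        ok2 <- if (length(s1) > 1L) s2 else setdiff(s2, s1)
        acc_keys[[j]] <- c(edge_key(x, y),
                           if (length(ok1)) edge_key(rep(x, length(ok1)), ok1),
                           if (length(ok2)) edge_key(rep(y, length(ok2)), ok2))
        acc_int[[j]] <- c(x, y)
      }
      keys <- c(keys, unlist(acc_keys, use.names = FALSE))
      intermediates <- c(intermediates,
                         unlist(acc_int, use.names = FALSE))
    }
  }

  keys <- sort(unique(keys))
  ends <- if (length(keys)) split_edge_key(keys)
          else matrix(character(0), ncol = 2L)
  edges <- data.frame(node_a = ends[, 1], node_b = ends[, 2],
                      stringsAsFactors = FALSE)
  touched <- unique(c(edges$node_a, edges$node_b))
  out <- list(seed_nodes = sort(intersect(touched, s_in)),
              intermediate_nodes = sort(unique(intermediates)),
              edges = edges,
              all_seeds = sort(s_in),
              unmapped_seeds = unmapped,
              max_intermediates = max_intermediates)
  class(out) <- "subnetwork"
  out
}

#' Summarize a subnetwork
#'
#' @param sub A `"subnetwork"` from [expand_subnetwork()].
#' @return A list with `n_seed_connected` (seeds incident to at least one
#'   subnetwork edge), `n_intermediates`, and `n_edges`.
#' @export
subnetwork_summary <- function(sub) {
  stopifnot(inherits(sub, "subnetwork"))
  list(n_seed_connected = length(sub$seed_nodes),
       n_intermediates = length(sub$intermediate_nodes),
       n_edges = nrow(sub$edges))
}

#' @export
print.subnetwork <- function(x, ...) {
  s <- subnetwork_summary(x)
  cat(sprintf(
    "subnetwork: %d interactions among %d seed proteins, using %d intermediates\n",
    s$n_edges, s$n_seed_connected, s$n_intermediates))
  if (length(x$unmapped_seeds))
    cat(sprintf("  unmapped seeds: %s\n",
                paste(x$unmapped_seeds, collapse = ", ")))
  invisible(x)
}

#' Write a subnetwork as SIF plus node-role attributes
#'
#' Writes `<prefix>.sif` (edges), `<prefix>_nodes.tsv` (node, role) with
#' roles `seed` / `intermediate`, and `<prefix>_summary.json`.
#'
#' @param sub A `"subnetwork"`.
#' @param path_prefix Output path prefix.
#' @return `path_prefix`, invisibly.
#' @export
write_subnetwork <- function(sub, path_prefix) {
  stopifnot(inherits(sub, "subnetwork"))
  writeLines(sprintf("%s\tpp\t%s", sub$edges$node_a, sub$edges$node_b),
             paste0(path_prefix, ".sif"))
  nodes <- data.frame(
    node = c(sub$seed_nodes, sub$intermediate_nodes),
    role = rep(c("seed", "intermediate"),
               c(length(sub$seed_nodes), length(sub$intermediate_nodes))),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  write.table(nodes, paste0(path_prefix, "_nodes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(subnetwork_summary(sub),
                         list(unmapped_seeds = sub$unmapped_seeds)),
                       paste0(path_prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path_prefix)
}
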