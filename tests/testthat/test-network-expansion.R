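# Seed-subnetwork expansion through at most two non-seed intermediates.

path_net <- function(...) {
  nodes <- c(...)
  make_net(cbind(nodes[-length(nodes)], nodes[-1]))
}

test_that("direct connections and two-intermediate paths are recovered", {
  # direct seed-seed edge
  net <- path_net("A", "B")
  sub <- expand_subnetwork(c("A", "B"), net)
  expect_equal(subnetwork_summary(sub),
               list(n_seed_connected = 2L, n_intermediates = 0L,
                    n_edges = 1L))

  # A-x-y-B: two intermediates, three links
  net2 <- path_net("A", "X", "Y", "B")
  sub2 <- expand_subnetwork(c("A", "B"), net2)
  expect_setequal(sub2$intermediate_nodes, c("X", "Y"))
  expect_equal(nrow(sub2$edges), 3L)

  # A-x-y-z-B exceeds the path bound: nothing qualifies
  net3 <- path_net("A", "X", "Y", "Z", "B")
  sub3 <- expand_subnetwork(c("A", "B"), net3)
  expect_equal(subnetwork_summary(sub3),
               list(n_seed_connected = 0L, n_intermediates = 0L,
                    n_edges = 0L))

  # seeds missing from the background are reported
  expect_identical(sub2$unmapped_seeds, character(0))
  sub4 <- expand_subnetwork(c("A", "B", "QQQ"), net2)
  expect_identical(sub4$unmapped_seeds, "QQQ")
  expect_error(expand_subnetwork(c("A", "B"),
                                 structure(list(nodes = character(0),
                                                edges = data.frame()),
                                           class = "background_network")),
               "empty")
})

test_that("paths through seeds decompose at the seed", {
  # A-x-B-y-C with B a seed: A..C via x-B-y has a seed interior, but the
  # segments A-x-B and B-y-C qualify on their own
  net <- path_net("A", "X", "B", "Y", "C")
  sub <- expand_subnetwork(c("A", "B", "C"), net)
  expect_setequal(sub$intermediate_nodes, c("X", "Y"))
  expect_equal(nrow(sub$edges), 4L)

  # a dead-end neighbor of a single seed is not an intermediate
  net2 <- make_net(rbind(c("A", "D"), c("A", "X"), c("X", "B")))
  sub2 <- expand_subnetwork(c("A", "B"), net2)
  expect_identical(sub2$intermediate_nodes, "X")
  expect_false("D" %in% c(sub2$edges$node_a, sub2$edges$node_b))
})

test_that("max_intermediates = 0 gives exactly the induced seed-seed edges", {
  set.seed(7)
  g <- named_er_graph(40, 0.15, seed = 7)
  edges <- igraph::as_edgelist(g)
  net <- make_net(edges)
  seeds <- sprintf("N%03d", c(1, 5, 9, 13, 17, 21))
  sub <- expand_subnetwork(seeds, net, max_intermediates = 0)
  both <- edges[edges[, 1] %in% seeds & edges[, 2] %in% seeds, ,
                drop = FALSE]
  expect_equal(nrow(sub$edges), nrow(both))
  expect_equal(length(sub$intermediate_nodes), 0L)
})

test_that("expansion equals exhaustive simple-path enumeration", {
  for (seed in 1:6) {
    g <- named_er_graph(60, 0.05, seed = seed)
    net <- make_net(igraph::as_edgelist(g))
    set.seed(seed + 100)
    seeds <- sample(igraph::V(g)$name, 6)
    sub <- expand_subnetwork(seeds, net)
    oracle <- oracle_expand(seeds, g)
    got_edges <- sort(paste(sub$edges$node_a, sub$edges$node_b, sep = "::"))
    expect_identical(got_edges, oracle$edges)
    expect_identical(sub$intermediate_nodes, oracle$intermediates)
  }
})

test_that("growing the path budget never removes nodes or edges", {
  for (seed in 1:4) {
    g <- named_er_graph(50, 0.06, seed = seed + 30)
    net <- make_net(igraph::as_edgelist(g))
    set.seed(seed)
    seeds <- sample(igraph::V(g)$name, 5)
    subs <- lapply(0:2, function(m)
      expand_subnetwork(seeds, net, max_intermediates = m))
    for (m in 1:2) {
      prev <- paste(subs[[m]]$edges$node_a, subs[[m]]$edges$node_b)
      curr <- paste(subs[[m + 1]]$edges$node_a, subs[[m + 1]]$edges$node_b)
      expect_true(all(prev %in% curr))
      expect_true(all(subs[[m]]$intermediate_nodes %in%
                        subs[[m + 1]]$intermediate_nodes))
    }
  }
})

test_that("every intermediate lies on a short seed-to-seed path", {
  g <- named_er_graph(80, 0.05, seed = 77)
  net <- make_net(igraph::as_edgelist(g))
  seeds <- sprintf("N%03d", seq(1, 30, by = 3))
  sub <- expand_subnetwork(seeds, net)
  if (length(sub$intermediate_nodes)) {
    gs <- as_igraph(sub)
    s_in <- sub$seed_nodes
    for (x in sub$intermediate_nodes) {
      on_path <- FALSE
      for (s in s_in) {
        d <- igraph::distances(gs, v = x, to = setdiff(s_in, s))
        if (igraph::are_adjacent(gs, x, s) && any(d <= 2)) {
          on_path <- TRUE
          break
        }
      }
      expect_true(on_path, info = x)
    }
  }
})
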