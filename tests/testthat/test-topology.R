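graph_from_edges <- function(nodes, edges) {
  fixture_to_igraph(list(nodes = nodes, edges = edges))
}

test_that("degree centrality on canonical small graphs", {
  tri <- graph_from_edges(c("a", "b", "c"),
                          rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(degree_centrality(tri), c(a = 2L, b = 2L, c = 2L))
  star <- graph_from_edges(c("h", "l1", "l2", "l3", "l4"),
                           cbind("h", c("l1", "l2", "l3", "l4")))
  dc <- degree_centrality(star)
  expect_equal(unname(dc["h"]), 4L)
  expect_true(all(dc[c("l1", "l2", "l3", "l4")] == 1L))
  # handshake identity
  expect_equal(sum(dc), 2L * igraph::ecount(star))
})

test_that("betweenness on a path, a complete graph, and tiny graphs", {
  path <- graph_from_edges(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  bc <- betweenness_centrality(path)
  expect_equal(bc, c(A = 0, B = 1, C = 0))
  k4 <- fixture_to_igraph(list(nodes = letters[1:4],
                               edges = t(combn(letters[1:4], 2))))
  expect_true(all(betweenness_centrality(k4) == 0))
  # n < 3 is all zeros by convention
  expect_equal(unname(betweenness_centrality(
    graph_from_edges(c("a", "b"), rbind(c("a", "b"))))), c(0, 0))
  # normalization divides by (n-1)(n-2)/2
  expect_equal(unname(betweenness_centrality(path, normalized = TRUE)["B"]), 1)
})

test_that("component-scaled closeness follows the stated formula", {
  path <- graph_from_edges(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  cc <- closeness_centrality(path)
  expect_equal(cc, c(A = 2 / 3, B = 1, C = 2 / 3))
  # two disjoint edges in a 4-node graph: (1/3) * (1/1) each
  two <- graph_from_edges(c("a", "b", "c", "d"),
                          rbind(c("a", "b"), c("c", "d")))
  expect_equal(unname(closeness_centrality(two)), rep(1 / 3, 4))
  # isolated node scores zero
  iso <- graph_from_edges(c("a", "b", "x"), rbind(c("a", "b")))
  expect_equal(unname(closeness_centrality(iso)["x"]), 0)
})

test_that("centralities match the naive all-pairs-BFS oracle on random graphs", {
  set.seed(21)
  for (rep in 1:25) {
    fx <- random_graph_fixture(sample(4:25, 1), p = runif(1, 0.1, 0.4))
    g <- fixture_to_igraph(fx)
    orc <- oracle_centralities(fx)
    expect_equal(as.numeric(degree_centrality(g)[fx$nodes]),
                 unname(orc$dc[fx$nodes]))
    expect_equal(as.numeric(betweenness_centrality(g)[fx$nodes]),
                 unname(orc$bc[fx$nodes]), tolerance = 1e-10)
    expect_equal(as.numeric(closeness_centrality(g)[fx$nodes]),
                 unname(orc$cc[fx$nodes]), tolerance = 1e-10)
  }
})

test_that("median screen: star graph keeps its hub, complete graph keeps nothing", {
  star <- graph_from_edges(c("h", "l1", "l2", "l3", "l4"),
                           cbind("h", c("l1", "l2", "l3", "l4")))
  res <- median_screen(star)
  # degrees (4,1,1,1,1): median 1, threshold 2 -> hub = {h}; the singleton
  # subgraph trivially meets its own medians
  expect_equal(res$hub_nodes, "h")
  expect_equal(res$core_targets, "h")
  expect_equal(res$thresholds$stage1_threshold, 2)

  k5 <- fixture_to_igraph(list(nodes = letters[1:5],
                               edges = t(combn(letters[1:5], 2))))
  expect_warning(res5 <- median_screen(k5), "empty")
  expect_length(res5$core_targets, 0)
  expect_length(res5$hub_nodes, 0)
  expect_error(median_screen(igraph::make_empty_graph(directed = FALSE)),
               "empty")
})

test_that("strict stage-1 comparison excludes exact-threshold ties", {
  # two nodes at exactly twice the median degree
  g <- graph_from_edges(c("x", "y", "a", "b", "c", "d"),
                        rbind(c("x", "a"), c("x", "b"), c("y", "c"),
                              c("y", "d"), c("x", "y")))
  # degrees: x=3,y=3,a=b=c=d=1 -> median 1, threshold 2
  loose <- median_screen(g)
  strict <- median_screen(g, strict_hub = TRUE)
  expect_setequal(loose$hub_nodes, c("x", "y"))
  expect_setequal(strict$hub_nodes, c("x", "y"))   # 3 > 2 still
  g2 <- graph_from_edges(c("x", "a", "b", "u", "v"),
                         rbind(c("x", "a"), c("x", "b"), c("u", "v")))
  # degrees: x=2,a=1,b=1,u=1,v=1 -> median 1, threshold 2; x ties exactly
  expect_equal(median_screen(g2)$hub_nodes, "x")
  expect_warning(s2 <- median_screen(g2, strict_hub = TRUE), "empty")
  expect_length(s2$hub_nodes, 0)
})

test_that("a planted densely wired clique is recovered as the core", {
  fx <- planted_clique_fixture(core_size = 6, n_periph = 30)
  g <- fixture_to_igraph(fx)
  res <- median_screen(g)
  expect_true(all(fx$core %in% res$core_targets))
  expect_true(all(res$core_targets %in% res$hub_nodes))
})

test_that("screen is invariant to bc rescaling, relabeling, and row order", {
  set.seed(33)
  for (rep in 1:15) {
    fx <- random_graph_fixture(sample(8:20, 1), p = runif(1, 0.15, 0.5))
    g <- fixture_to_igraph(fx)
    base <- suppressWarnings(median_screen(g))
    # toggling betweenness normalization never changes the screened sets
    norm <- suppressWarnings(median_screen(g, bc_normalized = TRUE))
    expect_identical(norm$hub_nodes, base$hub_nodes)
    expect_identical(norm$core_targets, base$core_targets)
    # node relabeling permutes but never changes the sets
    perm <- setNames(sprintf("Z%02d", sample(seq_along(fx$nodes))), fx$nodes)
    fx2 <- list(nodes = unname(perm[fx$nodes]),
                edges = matrix(perm[fx$edges], ncol = 2))
    relab <- suppressWarnings(median_screen(fixture_to_igraph(fx2)))
    expect_setequal(relab$hub_nodes, unname(perm[base$hub_nodes]))
    expect_setequal(relab$core_targets, unname(perm[base$core_targets]))
    # edge-row shuffling changes nothing
    if (nrow(fx$edges) > 1) {
      fx3 <- list(nodes = fx$nodes,
                  edges = fx$edges[sample(nrow(fx$edges)), , drop = FALSE])
      shuf <- suppressWarnings(median_screen(fixture_to_igraph(fx3)))
      expect_identical(shuf$hub_nodes, base$hub_nodes)
      expect_identical(shuf$core_targets, base$core_targets)
    }
    expect_true(all(base$core_targets %in% base$hub_nodes))
  }
})
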