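test_that("edge-list parsing collapses duplicates and drops self-loops", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb", "b\ta", "a\ta", "b\tc"), f)
  expect_warning(g <- read_edge_list(f), "self-loop")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "b", "c"))

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  g0 <- read_edge_list(empty)
  expect_equal(igraph::vcount(g0), 0)
  expect_equal(igraph::ecount(g0), 0)

  tri <- withr::local_tempfile()
  writeLines(c("# comment", "x\ty", "y\tz", "z\tx"), tri)
  gt <- read_edge_list(tri)
  expect_equal(c(igraph::vcount(gt), igraph::ecount(gt)), c(3, 3))
})

test_that("malformed lines are reported with their line number", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb", "c"), f)
  expect_error(read_edge_list(f), "line 2")
  s <- withr::local_tempfile()
  writeLines(c("a pp b", "b pp c", "c pp a"), s)
  gs <- read_edge_list(s, format = "sif")
  expect_equal(igraph::ecount(gs), 3)
  expect_error(read_edge_list(s, format = "tsv"), "line 1")
})

test_that("giant component extraction and its tie rule", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb", "b\tc", "c\ta", "x\ty"), f)
  g <- read_edge_list(f)
  gc <- giant_component(g)
  expect_setequal(igraph::V(gc)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(gc), 3)

  # connected graph: identity
  expect_equal(igraph::vcount(giant_component(gc)), 3)

  # equal-size components: the one holding the smallest id wins
  h <- igraph::graph_from_edgelist(rbind(c("c", "d"), c("a", "b")), directed = FALSE)
  expect_setequal(igraph::V(giant_component(h))$name, c("a", "b"))
  expect_error(giant_component(igraph::make_empty_graph(0)), "empty")
})

test_that("degrees satisfy the handshake lemma and known cases", {
  tri <- make_clique(c("a", "b", "c"))
  expect_true(all(node_degrees(tri) == 2))
  star <- igraph::graph_from_edgelist(cbind("hub", paste0("l", 1:4)), directed = FALSE)
  expect_equal(unname(node_degrees(star)["hub"]), 4)
  expect_true(all(node_degrees(star)[paste0("l", 1:4)] == 1))
  for (i in 1:5) {
    g <- rand_graph(10, 0.3, min_edges = 0)
    expect_equal(sum(node_degrees(g)), 2 * igraph::ecount(g))
  }
})

test_that("clustering coefficient matches neighbor-pair enumeration", {
  tri <- make_clique(c("a", "b", "c"))
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  star <- igraph::graph_from_edgelist(cbind("hub", paste0("l", 1:4)), directed = FALSE)
  expect_equal(unname(clustering_coefficient(star, "hub")), 0)
  expect_equal(unname(clustering_coefficient(star, "l1")), 0)  # degree-1 convention
  # node v with neighbors x, y, z and a single x-y edge: 1/3
  g <- igraph::graph_from_edgelist(
    rbind(c("v", "x"), c("v", "y"), c("v", "z"), c("x", "y")), directed = FALSE)
  expect_equal(unname(clustering_coefficient(g, "v")), 1 / 3)
  expect_error(clustering_coefficient(g, "nope"), "unknown")
  for (i in 1:5) {
    cc <- clustering_coefficient(rand_graph(9, 0.4, min_edges = 0))
    expect_true(all(cc >= 0 & cc <= 1))
  }
})

test_that("betweenness follows the pair-based unnormalized convention", {
  p3 <- path_graph_named(c("a", "b", "c"))
  expect_equal(unname(betweenness_centrality(p3)["b"]), 1)
  p5 <- path_graph_named(letters[1:5])
  expect_equal(unname(betweenness_centrality(p5)["c"]), 4)
  expect_equal(unname(betweenness_centrality(p5)["a"]), 0)
  k5 <- make_clique(letters[1:5])
  expect_true(all(betweenness_centrality(k5) == 0))
  star <- igraph::graph_from_edgelist(cbind("hub", paste0("l", 1:6)), directed = FALSE)
  expect_equal(unname(betweenness_centrality(star)["hub"]), choose(6, 2))
})

test_that("bridging centrality matches hand evaluation and brute force", {
  p5 <- path_graph_named(letters[1:5])
  br <- bridging_centrality(p5)
  expect_equal(br$bridging_coefficient[br$node == "c"], 0.5)
  expect_equal(br$bridging_centrality[br$node == "c"], 2.0)
  star <- igraph::graph_from_edgelist(cbind("hub", paste0("l", 1:4)), directed = FALSE)
  bs <- bridging_centrality(star)
  expect_equal(bs$bridging_coefficient[bs$node == "hub"], 0.0625)
  expect_equal(bs$bridging_centrality[bs$node == "hub"], 0.375)
  expect_equal(br$bridging_centrality[br$node == "a"], 0)

  set.seed(41)
  for (i in 1:10) {
    g <- rand_graph(sample(5:8, 1), 0.5, connected = TRUE)
    tab <- bridging_centrality(g)
    be <- betweenness_centrality(g)
    k <- igraph::degree(g)
    for (v in igraph::V(g)$name) {
      nb <- names(igraph::neighbors(g, v))
      bc_direct <- (1 / k[[v]]) / sum(1 / k[nb])
      expect_equal(tab$bridging_coefficient[tab$node == v], unname(bc_direct), tolerance = 1e-12)
      expect_equal(tab$bridging_centrality[tab$node == v],
                   unname(bc_direct * be[[v]]), tolerance = 1e-12)
    }
  }
})

test_that("centrality table is total and round-trips through TSV", {
  g <- rand_graph(8, 0.5, connected = TRUE)
  tab <- centrality_table(g)
  expect_equal(nrow(tab), 8)
  expect_named(tab, c("node", "degree", "clustering", "betweenness",
                      "bridging_coefficient", "bridging_centrality"))
  f <- withr::local_tempfile()
  write_centrality_table(tab, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$degree, tab$degree)
  expect_equal(back$betweenness, tab$betweenness, tolerance = 1e-9)
})
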