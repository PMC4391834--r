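test_that("ring of cliques matches its closed-form counts", {
  rc <- ring_of_cliques(4, 3)
  expect_equal(igraph::vcount(rc$network), 12)
  expect_equal(igraph::ecount(rc$network), 4 * 3 + 4)
  st <- cluster_stats(rc$network, rc$truth$micro)
  expect_true(all(st$l_int == choose(3, 2)))
  expect_true(all(st$l_out == 2))
  expect_error(ring_of_cliques(2, 5), "n_cliques")
  expect_error(ring_of_cliques(5, 2), "clique_size")
  for (k in c(4, 6)) {
    rr <- ring_of_cliques(5, k)
    expect_equal(igraph::ecount(rr$network), 5 * choose(k, 2) + 5)
  }
})

test_that("the large clique ring sits in the resolution-limit regime", {
  rc <- ring_of_cliques(30, 5)
  net <- rc$network
  per_clique <- rc$truth$micro
  # merge consecutive clique pairs
  idx <- as.integer(sub("clique", "", per_clique))
  merged <- stats::setNames(sprintf("pair%02d", (idx - 1) %/% 2), names(per_clique))
  expect_gt(modularity_q(net, merged), modularity_q(net, per_clique))
})

test_that("hierarchical generator output is seeded, nested and connected", {
  h1 <- hierarchical_planted_graph(seed = 3)
  h2 <- hierarchical_planted_graph(seed = 3)
  expect_identical(igraph::as_edgelist(h1$network), igraph::as_edgelist(h2$network))
  expect_true(igraph::is_connected(h1$network))
  # micro refines macro structurally
  span <- tapply(h1$truth$macro, h1$truth$micro, function(x) length(unique(x)))
  expect_true(all(span == 1))
  expect_error(hierarchical_planted_graph(p_in_micro = 0.1, p_in_macro = 0.2),
               "p_in_micro")
  expect_equal(h1$truth$params$p_in_micro, 0.6)
  expect_length(h1$truth$interface, 12)
})

test_that("block-model edge counts match binomial expectations", {
  set.seed(6)
  counts <- replicate(20, {
    hh <- hierarchical_planted_graph(n_interface = 0, seed = sample.int(1e6, 1))
    igraph::ecount(hh$network)
  })
  # expected edges: 16 within-micro blocks + 4*6 within-macro micro pairs
  # + 96 cross-macro micro pairs
  mu <- 16 * choose(12, 2) * 0.6 + 24 * 144 * 0.04 + 96 * 144 * 0.003
  v <- 16 * choose(12, 2) * 0.6 * 0.4 + 24 * 144 * 0.04 * 0.96 + 96 * 144 * 0.003 * 0.997
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(v / 20))
})

test_that("interface nodes land in the kinless region of the Z-P plane", {
  hh <- hierarchical_planted_graph(seed = 10)
  carto <- cartography_table(hh$network, hh$truth$micro)
  iface <- carto[carto$node %in% hh$truth$interface, ]
  expect_true(all(iface$p > 0.6))
  expect_gte(mean(iface$role == "R4"), 0.8)
})

test_that("interface gene sets carry the planted participation and degree bias", {
  hh <- hierarchical_planted_graph(seed = 8)
  net <- hh$network
  part <- hh$truth$micro
  u1 <- planted_interface_geneset(net, part, 40, beta = 0, gamma = 0, seed = 5)
  u2 <- planted_interface_geneset(net, part, 40, beta = 0, gamma = 0, seed = 5)
  expect_identical(u1, u2)
  expect_error(planted_interface_geneset(net, part, 10000, seed = 1), "size")

  p <- participation(net, part)
  wins <- 0
  for (s in 1:10) {
    gs <- planted_interface_geneset(net, part, 40, beta = 5, gamma = 0, seed = s)
    if (mean(p[gs]) > mean(p)) wins <- wins + 1
  }
  expect_equal(wins, 10)

  k <- igraph::degree(net)
  gs2 <- planted_interface_geneset(net, part, 40, beta = 5, gamma = 1, seed = 77)
  expect_gt(mean(k[gs2]), mean(k))
})

test_that("module-aligned annotations interpolate between perfect and random", {
  hh <- hierarchical_planted_graph(seed = 17)
  ann0 <- module_aligned_annotations(hh$truth, noise = 0, seed = 1)
  expect_equal(bhi(hh$truth$micro, ann0), 1)
  ann <- module_aligned_annotations(hh$truth, noise = 0.2, seed = 2)
  expect_gt(bhi(hh$truth$micro, ann), bhi(hh$truth$macro, ann))
  a1 <- module_aligned_annotations(hh$truth, noise = 0.5, seed = 9)
  a2 <- module_aligned_annotations(hh$truth, noise = 0.5, seed = 9)
  expect_identical(a1, a2)
})
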