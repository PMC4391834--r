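test_that("within-module degree Z uses population sd and the sd=0 convention", {
  k5 <- make_clique(letters[1:5])
  one <- stats::setNames(rep("m", 5), letters[1:5])
  expect_true(all(within_module_degree_z(k5, one) == 0))

  # community degrees {3,2,2,1}: Z of the degree-3 node = 1/sqrt(0.5)
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c")), directed = FALSE)
  z <- within_module_degree_z(g, stats::setNames(rep("m", 4), letters[1:4]))
  expect_equal(unname(z["a"]), (3 - 2) / sqrt(0.5), tolerance = 1e-12)

  # two identical communities -> identical Z profiles (label invariance)
  gg <- igraph::disjoint_union(g, igraph::set_vertex_attr(g, "name", value = paste0(letters[1:4], "2")))
  part2 <- stats::setNames(rep(c("u", "v"), each = 4), igraph::V(gg)$name)
  z2 <- within_module_degree_z(gg, part2)
  expect_equal(unname(z2[letters[1:4]]), unname(z2[paste0(letters[1:4], "2")]))
})

test_that("participation matches hand-computed link splits", {
  # k=2 split across two communities -> 0.5; internal-only -> 0
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("c", "e")), directed = FALSE)
  part <- stats::setNames(c("x", "x", "y", "y", "y"), letters[1:5])
  p <- participation(g, part)
  expect_equal(unname(p["b"]), 0.5)
  expect_equal(unname(p["d"]), 0)
  # c has k=3 split (2,1): P = 1 - (4/9 + 1/9)
  expect_equal(unname(p["c"]), 4 / 9, tolerance = 1e-12)
})

test_that("participation respects its combinatorial bounds", {
  set.seed(19)
  for (i in 1:8) {
    g <- rand_graph(12, 0.4, min_edges = 3)
    part <- rand_partition(igraph::V(g)$name, 3)
    p <- participation(g, part)
    k <- igraph::degree(g)
    M <- length(unique(part))
    for (v in names(p)) {
      if (k[[v]] == 0) next
      expect_lte(p[[v]], 1 - 1 / min(k[[v]], M) + 1e-12)
      expect_gte(p[[v]], 0)
    }
  }
})

test_that("merging communities never increases participation", {
  set.seed(23)
  for (i in 1:5) {
    g <- rand_graph(14, 0.35, min_edges = 4)
    part <- rand_partition(igraph::V(g)$name, 4)
    labs <- unique(part)
    if (length(labs) < 2) next
    merged <- part
    merged[merged == labs[2]] <- labs[1]
    expect_true(all(participation(g, merged) <= participation(g, part) + 1e-12))
  }
})

test_that("role thresholds pin every boundary", {
  cases <- list(
    list(z = -0.5, p = 0.0, role = "R1"),
    list(z = 0, p = 0.049, role = "R1"),
    list(z = 0, p = 0.05, role = "R2"),
    list(z = 2.499, p = 0.3, role = "R2"),
    list(z = 0, p = 0.624, role = "R2"),
    list(z = 0, p = 0.625, role = "R3"),
    list(z = 1.0, p = 0.799, role = "R3"),
    list(z = 1.0, p = 0.8, role = "R4"),
    list(z = 1.0, p = 0.85, role = "R4"),
    list(z = 2.5, p = 0.0, role = "R5"),
    list(z = 3.0, p = 0.299, role = "R5"),
    list(z = 2.5, p = 0.3, role = "R6"),
    list(z = 3.0, p = 0.5, role = "R6"),
    list(z = 2.5, p = 0.749, role = "R6"),
    list(z = 10, p = 0.75, role = "R7")
  )
  for (cs in cases) expect_equal(assign_role(cs$z, cs$p), cs$role)
  expect_error(assign_role(0, 1.0), "\\[0, 1\\)")
  expect_error(assign_role(0, -0.1), "\\[0, 1\\)")
})

test_that("cartography table composes the pieces and counts roles", {
  rc <- ring_of_cliques(8, 5)
  carto <- cartography_table(rc$network, rc$truth$micro)
  expect_equal(nrow(carto), 40)
  # interior clique nodes have all links internal -> R1; two contacts per clique
  contact <- grepl("_n001$|_n002$", carto$node)
  expect_true(all(carto$role[!contact] == "R1"))
  expect_true(all(carto$p[contact] > 0))
  rcounts <- role_counts(carto)
  expect_equal(sum(rcounts), 40)
  expect_equal(unname(rcounts["R1"]), sum(!contact))

  h <- zp_histogram(carto)
  expect_equal(sum(h), 40)
})

test_that("coarser partitions shift participation downward", {
  hh <- hierarchical_planted_graph(seed = 31)
  carto_f <- cartography_table(hh$network, hh$truth$micro)
  carto_c <- cartography_table(hh$network, hh$truth$macro)
  expect_gt(mean(carto_f$p), mean(carto_c$p))
})
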