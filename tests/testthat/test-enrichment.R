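test_that("enrichment p equals hypergeometric tail enumeration", {
  # exhaustive over all 2x2 tables with background <= 15
  for (N in 2:15) {
    for (K in 1:(N - 1)) {
      for (n in 1:(N - 1)) {
        ks <- max(0, K + n - N):min(K, n)
        for (k in ks) {
          expect_equal(fisher_enrichment_p(k, K, n, N),
                       oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment p agrees with fisher.test one-sided", {
  set.seed(8)
  for (i in 1:20) {
    N <- sample(10:40, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    m <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    expect_equal(fisher_enrichment_p(k, K, n, N),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("role enrichment table behaves on edge and toy cases", {
  hh <- hierarchical_planted_graph(seed = 1)
  carto <- cartography_table(hh$network, hh$truth$micro)
  expect_warning(tab <- fisher_role_enrichment(carto, character(0)), "empty")
  expect_true(all(tab$p_raw == 1))
  expect_equal(sum(tab$n_nodes), nrow(carto))

  gs <- carto$node[carto$role == "R4"]
  tab2 <- fisher_role_enrichment(carto, gs)
  expect_equal(sum(tab2$n_set), length(gs))
  expect_lt(tab2$p_adj[tab2$role == "R4"], 1e-6)
  # BH is monotone and bounded below by the raw p
  expect_true(all(tab2$p_adj >= tab2$p_raw - 1e-15))
  ord <- order(tab2$p_raw)
  expect_true(all(diff(tab2$p_adj[ord]) >= -1e-15))
})

test_that("degree-matched controls reproduce the degree multiset", {
  hh <- hierarchical_planted_graph(seed = 21)
  net <- hh$network
  deg <- igraph::degree(net)
  set.seed(5)
  ref <- sample(names(deg), 30)
  for (s in 1:5) {
    ctrl <- degree_matched_control_set(net, ref, seed = s)
    expect_equal(sort(as.numeric(deg[ctrl])), sort(as.numeric(deg[ref])))
    expect_equal(length(ctrl), 30)
  }
  expect_identical(degree_matched_control_set(net, ref, seed = 3),
                   degree_matched_control_set(net, ref, seed = 3))
})

test_that("degree bootstrap is deterministic and detects planted interface bias", {
  hh <- hierarchical_planted_graph(seed = 33)
  net <- hh$network
  fit <- infomap_cluster(net, seed = 34)
  carto <- cartography_table(net, as_partition(fit))
  # a set holding the full planted interface: kinless membership here is a
  # meso-scale property, not a degree property, so the degree-matched null
  # cannot reproduce it
  set.seed(35)
  gs <- union(hh$truth$interface,
              sample(setdiff(igraph::V(net)$name, hh$truth$interface), 48))
  b1 <- degree_bootstrap_pvalue(net, carto, gs, n = 100, seed = 36)
  b2 <- degree_bootstrap_pvalue(net, carto, gs, n = 100, seed = 36)
  expect_identical(b1$p_boot, b2$p_boot)
  expect_lte(b1$p_boot[b1$role == "R4"], 0.05)
  expect_true(all(b1$p_boot > 0 & b1$p_boot <= 1))
})

test_that("top-degree truncation follows the deterministic tie rule", {
  g <- igraph::graph_from_edgelist(do.call(rbind, lapply(1:10, function(i) {
    cbind(sprintf("v%02d", i), sprintf("u%02d_%d", i, seq_len(i)))
  })), directed = FALSE)  # v01..v10 have distinct degrees 1..10
  gs <- sprintf("v%02d", 1:10)
  out <- truncate_top_degree(gs, g, 0.1)
  expect_setequal(out, sprintf("v%02d", 1:9))
  expect_identical(truncate_top_degree(gs, g, 0), gs)

  # 20 members, ties across the cut: exactly 2 removed, reproducibly
  star_els <- do.call(rbind, lapply(1:20, function(i) {
    k <- if (i <= 17) 2 else 5
    cbind(sprintf("w%02d", i), sprintf("x%02d_%d", i, seq_len(k)))
  }))
  g2 <- igraph::graph_from_edgelist(star_els, directed = FALSE)
  gs2 <- sprintf("w%02d", 1:20)
  t1 <- truncate_top_degree(gs2, g2, 0.1)
  expect_equal(length(t1), 18)
  expect_identical(t1, truncate_top_degree(gs2, g2, 0.1))
  # among the tied top-degree members, lower ids are removed first
  expect_false("w18" %in% t1)
  expect_false("w19" %in% t1)
  expect_true("w20" %in% t1)
  expect_error(truncate_top_degree(character(0), g2), "empty")
})

test_that("degree-bounded subsetting uses the lower nearest-rank percentile", {
  # K4 plus one pendant: degrees p=1, a=4, b=c=d=3
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"),
          c("b", "d"), c("c", "d"), c("a", "p")), directed = FALSE)
  kept <- degree_bounded_nodes(g, 90)  # rank floor(4.5) = 4 -> cutoff 3
  expect_false("a" %in% kept)
  expect_setequal(kept, c("b", "c", "d", "p"))
  # just below 100%: only the strict maximum is dropped
  expect_false("a" %in% degree_bounded_nodes(g, 99.9))
  # regular graph: nobody removed
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- letters[1:8]
  expect_length(degree_bounded_nodes(ring, 90), 8)
})

test_that("AUC equals the Mann-Whitney estimate and anchors hold", {
  s <- c(a = 3, b = 1, c = 2, d = 0)
  r <- roc_auc(s, positives = c("a", "b"))
  expect_equal(r$auc, 0.75)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)

  perfect <- roc_auc(c(a = 9, b = 8, c = 1, d = 0), positives = c("a", "b"))
  expect_equal(perfect$auc, 1.0)
  flat <- roc_auc(c(a = 1, b = 1, c = 1, d = 1), positives = c("a", "b"))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_auc(s, positives = letters[1:4]), "positive")

  set.seed(12)
  for (i in 1:10) {
    sc <- stats::setNames(stats::rnorm(30), sprintf("n%02d", 1:30))
    sc[sample(30, 5)] <- round(sc[sample(30, 5)], 1)  # inject ties
    pos <- sample(names(sc), 8)
    auc <- roc_auc(sc, pos)$auc
    w <- stats::wilcox.test(sc[pos], sc[setdiff(names(sc), pos)], exact = FALSE)
    expect_equal(auc, unname(w$statistic) / (8 * 22), tolerance = 1e-12)
    cur <- roc_auc(sc, pos)$curve
    expect_true(all(diff(cur$fpr) >= 0) && all(diff(cur$tpr) >= 0))
  }
})

test_that("DeLong test matches pROC and handles identical scores", {
  s <- stats::setNames(c(3, 1, 2, 0, 5, 4, 2.5, 0.5), letters[1:8])
  dl0 <- delong_test(s, s, positives = c("a", "e", "f"))
  expect_equal(dl0$z, 0)
  expect_equal(dl0$p, 1)

  set.seed(14)
  for (i in 1:5) {
    n <- 40
    nodes <- sprintf("n%02d", 1:n)
    truthy <- sample(nodes, 12)
    sa <- stats::setNames(stats::rnorm(n) + (nodes %in% truthy), nodes)
    sb <- stats::setNames(stats::rnorm(n) + 0.5 * (nodes %in% truthy), nodes)
    dl <- delong_test(sa, sb, positives = truthy)
    labels <- as.integer(nodes %in% truthy)
    ra <- pROC::roc(labels, as.numeric(sa), quiet = TRUE, direction = "<")
    rb <- pROC::roc(labels, as.numeric(sb), quiet = TRUE, direction = "<")
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(dl$p, ref$p.value, tolerance = 1e-8)
    expect_equal(dl$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  }
})
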