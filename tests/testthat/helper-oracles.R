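# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's internal code paths: modularity is
# evaluated as the literal double sum over the adjacency matrix, codelength
# in entropy form, BHI by looping over ordered pairs, Fisher tails by
# explicit choose() sums.

# All set partitions of n items as integer membership vectors in restricted
# growth form (Bell(n) of them). Fine up to n = 8 (4140 partitions).
rgs_partitions <- function(n) {
  out <- list()
  rec <- function(m, kmax) {
    i <- length(m) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- m
      return(invisible())
    }
    for (v in seq_len(kmax + 1L)) rec(c(m, v), max(kmax, v))
  }
  rec(integer(0), 0L)
  out
}

# Literal Q = (1/2L) sum_ij (A_ij - k_i k_j / 2L) delta(C_i, C_j)
oracle_modularity <- function(net, part) {
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  nodes <- igraph::V(net)$name
  k <- rowSums(A)
  L <- sum(A) / 2
  lab <- part[nodes]
  delta <- outer(lab, lab, "==")
  sum((A - outer(k, k) / (2 * L)) * delta) / (2 * L)
}

# Two-level map-equation codelength in entropy form.
oracle_codelength <- function(net, part) {
  nodes <- igraph::V(net)$name
  L <- igraph::ecount(net)
  k <- igraph::degree(net)
  p <- k / (2 * L)
  lab <- part[nodes]
  H <- function(w) {
    w <- w[w > 0]
    if (!length(w)) return(0)
    w <- w / sum(w)
    -sum(w * log2(w))
  }
  el <- igraph::as_edgelist(net)
  mods <- unique(lab)
  q_m <- vapply(mods, function(m) {
    inm <- names(lab)[lab == m]
    sum(xor(el[, 1] %in% inm, el[, 2] %in% inm)) / (2 * L)
  }, numeric(1))
  q <- sum(q_m)
  idx <- if (q > 0) q * H(q_m) else 0
  mod_terms <- vapply(seq_along(mods), function(i) {
    rates <- c(q_m[i], p[names(lab)[lab == mods[i]]])
    sum(rates) * H(rates)
  }, numeric(1))
  idx + sum(mod_terms)
}

# Exhaustive minimum codelength over all set partitions (n <= 8).
oracle_min_codelength <- function(net) {
  nodes <- igraph::V(net)$name
  best <- Inf
  for (m in rgs_partitions(length(nodes))) {
    part <- stats::setNames(as.character(m), nodes)
    bits <- oracle_codelength(net, part)
    if (bits < best) best <- bits
  }
  best
}

# Exhaustive maximum modularity over all set partitions (n <= 7).
oracle_max_modularity <- function(net) {
  nodes <- igraph::V(net)$name
  best <- -Inf
  for (m in rgs_partitions(length(nodes))) {
    part <- stats::setNames(as.character(m), nodes)
    q <- oracle_modularity(net, part)
    if (q > best) best <- q
  }
  best
}

# BHI by explicit ordered-pair loops.
oracle_bhi <- function(part, ann) {
  ann <- ann[lengths(ann) > 0]
  annotated <- intersect(names(part), names(ann))
  comms <- split(annotated, part[annotated])
  comms <- comms[lengths(comms) >= 2]
  vals <- vapply(comms, function(members) {
    n <- length(members)
    hits <- 0L
    for (i in members) for (j in members) {
      if (i != j && length(intersect(ann[[i]], ann[[j]])) > 0) hits <- hits + 1L
    }
    hits / (n * (n - 1))
  }, numeric(1))
  mean(vals)
}

# Hypergeometric upper tail by explicit choose() sums.
oracle_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  xs <- xs[xs >= max(0, K + n - N)]
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Named Erdos-Renyi graph, optionally forced connected.
rand_graph <- function(n, p = 0.4, connected = FALSE, min_edges = 1) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    if (igraph::ecount(g) < min_edges) next
    if (!connected || igraph::is_connected(g)) return(g)
  }
}

rand_partition <- function(nodes, k = 3) {
  stats::setNames(as.character(sample.int(k, length(nodes), replace = TRUE)), nodes)
}

path_graph_named <- function(nodes) {
  el <- cbind(nodes[-length(nodes)], nodes[-1])
  igraph::graph_from_edgelist(el, directed = FALSE)
}

make_clique <- function(nodes) {
  pr <- utils::combn(nodes, 2)
  igraph::graph_from_edgelist(t(pr), directed = FALSE)
}
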