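#' Erdos-Renyi G(n, m) null model
#'
#' Uniformly sampled simple graph with exactly `n` nodes and `m` edges,
#' matching the node and edge counts of the network under study while
#' destroying all degree correlations.
#'
#' @param n Number of nodes.
#' @param m Number of edges; must satisfy `m <= n(n-1)/2`.
#' @param seed Integer seed (optional) for reproducibility.
#' @return An igraph graph with vertices named `v1..vn`.
#' @export
erdos_renyi_gnm <- function(n, m, seed = NULL) {
  if (m > n * (n - 1) / 2) stopf("m = %d exceeds the maximum %d for n = %d", m, n * (n - 1) / 2, n)
  g <- with_seed(seed, igraph::sample_gnm(n, m, directed = FALSE))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

#' Degree-preserving rewiring null model
#'
#' Randomizes a network by double-edge swaps: two edges (a,b), (c,d) are
#' replaced by (a,d), (c,b). A swap is rejected (and redrawn) if it would
#' create a self-loop or a duplicate edge, so the graph stays simple and every
#' node keeps its degree exactly. The result preserves the degree
#' distribution but destroys second- and higher-order correlations.
#'
#' @param net An igraph network with at least 2 edges.
#' @param swaps_per_edge Target number of accepted swaps per edge (default 10,
#'   a standard mixing heuristic for "fully rewired" ensembles).
#' @param seed Integer seed (optional).
#' @param max_attempts_per_edge Attempt cap (per edge) preventing
#'   non-termination on rigid graphs such as cliques.
#' @param verbose Log the acceptance rate via `message()`.
#' @return Rewired igraph graph on the same vertex set.
#' @export
degree_preserving_rewire <- function(net, swaps_per_edge = 10, seed = NULL,
                                     max_attempts_per_edge = 100, verbose = FALSE) {
  L <- igraph::ecount(net)
  if (L < 2) stopf("rewiring needs at least 2 edges")
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = FALSE)
  target <- ceiling(swaps_per_edge * L)
  max_attempts <- max_attempts_per_edge * L

  # adjacency hash for O(1) duplicate checks
  n <- length(nodes)
  key <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(L)) assign(as.character(key(el[e, 1], el[e, 2])), TRUE, envir = present)

  accepted <- 0L
  attempts <- 0L
  with_seed(seed, {
    while (accepted < target && attempts < max_attempts) {
      attempts <- attempts + 1L
      ij <- sample.int(L, 2L)
      e1 <- el[ij[1], ]
      e2 <- el[ij[2], ]
      if (stats::runif(1) < 0.5) e2 <- rev(e2)
      a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
      # proposed edges (a,d) and (c,b)
      if (a == d || c == b) next
      k1 <- as.character(key(a, d))
      k2 <- as.character(key(c, b))
      if (exists(k1, envir = present, inherits = FALSE) ||
          exists(k2, envir = present, inherits = FALSE) || k1 == k2) next
      rm(list = c(as.character(key(a, b)), as.character(key(c, d))), envir = present)
      assign(k1, TRUE, envir = present)
      assign(k2, TRUE, envir = present)
      el[ij[1], ] <- c(a, d)
      el[ij[2], ] <- c(c, b)
      accepted <- accepted + 1L
    }
  })
  if (verbose) {
    message(sprintf("rewiring: %d/%d swaps accepted in %d attempts (%.1f%% acceptance)",
                    accepted, target, attempts, if (attempts) 100 * accepted / attempts else 0))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::V(g)$name <- nodes
  attr(g, "rewire_accepted") <- accepted
  attr(g, "rewire_attempts") <- attempts
  g
}
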