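#' Per-community size and link statistics
#'
#' Classifies every edge as internal or boundary for each community of a
#' partition: `size` (nodes), `l_int` (edges with both ends inside) and
#' `l_out` (edges with exactly one end inside). Optionally adds `fbl`, the
#' fraction of a community's internal links that are *not* internal in a
#' reference partition ("broken links").
#'
#' @param net An igraph network.
#' @param part Partition covering the nodes.
#' @param reference Optional second partition for the `fbl` column.
#' @return Data frame with one row per community, sorted by decreasing size.
#' @export
cluster_stats <- function(net, part, reference = NULL) {
  part <- as_partition(part, net)
  el <- igraph::as_edgelist(net)
  ca <- part[el[, 1]]
  cb <- part[el[, 2]]
  comms <- sort(unique(part))
  lv <- factor(comms, levels = comms)
  internal <- ca == cb
  l_int <- table(factor(ca[internal], levels = comms))
  l_out <- table(factor(c(ca[!internal], cb[!internal]), levels = comms))
  size <- table(factor(part, levels = comms))
  out <- data.frame(community = comms,
                    size = as.integer(size),
                    l_int = as.integer(l_int),
                    l_out = as.integer(l_out),
                    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    reference <- as_partition(reference, net)
    ra <- reference[el[, 1]]
    rb <- reference[el[, 2]]
    broken <- internal & (ra != rb)
    n_broken <- table(factor(ca[broken], levels = comms))
    out$fbl <- ifelse(out$l_int > 0, as.integer(n_broken) / out$l_int, 0)
  }
  out[order(-out$size, out$community), , drop = FALSE]
}

#' Cumulative cluster-size curve
#'
#' Fraction of network nodes contained in communities with at most `x`
#' internal links, as a function of `x` (communities sharing an `l_int` value
#' are aggregated into one point). The curve is monotone non-decreasing and
#' terminates at exactly 1. An abrupt jump near the natural modularity scale
#' `sqrt(L)` is the signature of a dominant community size scale.
#'
#' @param stats A [cluster_stats()] table.
#' @param N Total node count of the network.
#' @return Data frame with columns `l_int` and `F` (cumulative node
#'   fraction).
#' @export
cumulative_cluster_size_curve <- function(stats, N) {
  agg <- tapply(stats$size, stats$l_int, sum)
  l <- as.numeric(names(agg))
  ord <- order(l)
  data.frame(l_int = l[ord], F = cumsum(as.numeric(agg)[ord]) / N)
}

#' Natural modularity scale of a network
#'
#' The resolution limit of modularity maximization sets a natural community
#' scale at about `lambda = sqrt(L)` internal links; communities smaller than
#' this tend to be merged. The symmetric band `[sqrt(L/2), sqrt(2L)]`
#' (equivalently `[lambda/sqrt(2), lambda*sqrt(2)]`) brackets the scale.
#'
#' @param net An igraph network with `L >= 1` edges.
#' @return List with `lambda` and the two-element `band`.
#' @export
natural_scale <- function(net) {
  L <- igraph::ecount(net)
  if (L < 1) stopf("natural scale undefined for an edgeless network")
  list(lambda = sqrt(L), band = c(sqrt(L / 2), sqrt(2 * L)))
}

#' Cross-partition overlap and nesting statistics
#'
#' Quantifies how much of one partition's intra-community structure is
#' preserved in another: the fraction of A-internal links also internal in B
#' (and vice versa), the fraction of intra-community node pairs of A that are
#' still intra-community in B (and vice versa, computed exactly by
#' per-cell binomial bookkeeping on the label contingency table), and the
#' per-A-community fraction of broken links relative to B. When B refines A,
#' the B-to-A fractions are exactly 1.
#'
#' @param net An igraph network.
#' @param part_a,part_b Partitions covering the nodes of `net`.
#' @return Object of class `partition_overlap`: list with fields
#'   `a_links_in_b`, `b_links_in_a`, `a_pairs_in_b`, `b_pairs_in_a`, and
#'   `fbl_a_vs_b` (named by A community).
#' @export
partition_overlap <- function(net, part_a, part_b) {
  part_a <- as_partition(part_a, net)
  part_b <- as_partition(part_b, net)
  el <- igraph::as_edgelist(net)
  int_a <- part_a[el[, 1]] == part_a[el[, 2]]
  int_b <- part_b[el[, 1]] == part_b[el[, 2]]
  a_links_in_b <- if (any(int_a)) sum(int_a & int_b) / sum(int_a) else NA_real_
  b_links_in_a <- if (any(int_b)) sum(int_a & int_b) / sum(int_b) else NA_real_
  nodes <- names(part_a)
  tab <- table(part_a[nodes], part_b[nodes])
  pairs_a <- sum(choose(rowSums(tab), 2))
  pairs_b <- sum(choose(colSums(tab), 2))
  pairs_both <- sum(choose(tab, 2))
  a_pairs_in_b <- if (pairs_a > 0) pairs_both / pairs_a else NA_real_
  b_pairs_in_a <- if (pairs_b > 0) pairs_both / pairs_b else NA_real_
  cs <- cluster_stats(net, part_a, reference = part_b)
  structure(list(a_links_in_b = a_links_in_b,
                 b_links_in_a = b_links_in_a,
                 a_pairs_in_b = a_pairs_in_b,
                 b_pairs_in_a = b_pairs_in_a,
                 fbl_a_vs_b = stats::setNames(cs$fbl, cs$community)),
            class = "partition_overlap")
}

#' @export
print.partition_overlap <- function(x, ...) {
  cat(sprintf(paste0("Partition overlap:\n",
                     "  A-internal links also internal in B: %.1f%%\n",
                     "  B-internal links also internal in A: %.1f%%\n",
                     "  A intra-community pairs preserved in B: %.1f%%\n",
                     "  B intra-community pairs preserved in A: %.1f%%\n"),
              100 * x$a_links_in_b, 100 * x$b_links_in_a,
              100 * x$a_pairs_in_b, 100 * x$b_pairs_in_a))
  invisible(x)
}
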