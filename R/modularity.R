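#' Newman modularity of a partition
#'
#' Evaluates
#' \deqn{Q = \frac{1}{2L}\sum_{ij}\left(A_{ij} - \frac{k_i k_j}{2L}\right)\delta(C_i, C_j)}
#' i.e. the fraction of edges falling within communities minus the expectation
#' under the degree-preserving configuration null model. Computed exactly via
#' the equivalent community sum \eqn{\sum_c [l_c/L - (d_c/2L)^2]} with
#' \eqn{l_c} the internal edge count and \eqn{d_c} the total degree of
#' community \eqn{c}. The single-community partition gives exactly 0.
#'
#' @param net An igraph network with at least one edge.
#' @param part Partition covering exactly the nodes of `net`
#'   (see [as_partition()]).
#' @return Modularity Q, a number in `[-1, 1]`.
#' @export
modularity_q <- function(net, part) {
  part <- as_partition(part, net)
  L <- igraph::ecount(net)
  if (L < 1) stopf("modularity requires at least one edge")
  el <- igraph::as_edgelist(net)
  ca <- part[el[, 1]]
  cb <- part[el[, 2]]
  l_c <- table(factor(ca[ca == cb], levels = unique(part)))
  k <- igraph::degree(net)
  d_c <- tapply(k[names(part)], part, sum)
  sum(as.numeric(l_c[names(d_c)]) / L - (as.numeric(d_c) / (2 * L))^2)
}
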