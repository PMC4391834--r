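#' Greedy modularity clustering (Clauset-Newman-Moore)
#'
#' Agglomerative modularity maximization: starting from singleton
#' communities, the pair of connected communities whose merge yields the
#' largest modularity gain \eqn{\Delta Q = l_{ab}/L - 2 a_a a_b} (with
#' \eqn{a_c = d_c/2L}) is merged repeatedly until a single community remains
#' (or no connected pair is left on disconnected input). The partition at the
#' maximum Q along the merge path is returned together with the full
#' dendrogram trace. Only connected community pairs are considered, since
#' merging disconnected communities can never increase Q.
#'
#' The procedure is fully deterministic: \eqn{\Delta Q} ties are broken by the
#' lexicographically smallest `(labelA, labelB)` pair, and a merged community
#' inherits the smaller of the two labels. Initial labels are the node ids.
#'
#' @param net An igraph network with at least one edge.
#' @return Object of class `cnm_communities`: a list with elements
#'   `membership` (named character vector), `modularity` (Q at the returned
#'   cut, re-verified with [modularity_q()]), `n_communities`, `trace`
#'   (data frame `step, labelA, labelB, dQ, Q`), and `algorithm = "cnm"`.
#' @export
cnm_cluster <- function(net) {
  N <- igraph::vcount(net)
  L <- igraph::ecount(net)
  if (N == 0) stopf("cannot cluster an empty network")
  nodes <- igraph::V(net)$name
  if (L == 0) {
    membership <- stats::setNames(nodes, nodes)
    return(structure(list(membership = membership, modularity = NA_real_,
                          n_communities = N,
                          trace = data.frame(step = integer(), labelA = character(),
                                             labelB = character(), dQ = numeric(),
                                             Q = numeric(), stringsAsFactors = FALSE),
                          algorithm = "cnm"),
                     class = "cnm_communities"))
  }
  k <- igraph::degree(net)
  a <- as.numeric(k) / (2 * L)          # a_c = d_c / 2L per community
  labels <- nodes                        # current label of community i
  active <- rep(TRUE, N)
  # nbr[[i]]: named numeric vector, edge counts to other communities
  # (simple graph, so every initial count is 1)
  adj <- igraph::as_adj_list(net)
  nbr <- lapply(adj, function(js) {
    js <- as.integer(js)
    stats::setNames(rep(1, length(js)), as.character(js))
  })
  getw <- function(v, nm) {
    x <- v[nm]
    if (length(x) == 0 || is.na(x)) 0 else as.numeric(x)
  }

  Q <- -sum(a^2)                         # singleton partition
  best_Q <- Q
  best_step <- 0L
  merges <- matrix(0L, nrow = 0, ncol = 2) # (survivor, absorbed) community ids
  trace <- list()
  step <- 0L
  repeat {
    # locate the best connected pair
    best_dq <- -Inf
    bi <- 0L; bj <- 0L
    for (i in which(active)) {
      js <- as.integer(names(nbr[[i]]))
      for (idx in seq_along(js)) {
        j <- js[idx]
        if (j <= i) next
        dq <- nbr[[i]][idx] / L - 2 * a[i] * a[j]
        if (dq > best_dq + 1e-12) {
          best_dq <- dq; bi <- i; bj <- j
        } else if (bi > 0L && dq >= best_dq - 1e-12) {
          # lexicographic tie-break on the sorted label pair
          cand <- sort(c(labels[i], labels[j]))
          cur <- sort(c(labels[bi], labels[bj]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            bi <- i; bj <- j
          }
        }
      }
    }
    if (bi == 0L) break                  # no connected pair left
    # survivor = community with the smaller label
    if (labels[bj] < labels[bi]) { tmp <- bi; bi <- bj; bj <- tmp }
    step <- step + 1L
    Q <- Q + best_dq
    lab_pair <- sort(c(labels[bi], labels[bj]))
    trace[[step]] <- data.frame(step = step, labelA = lab_pair[1],
                                labelB = lab_pair[2], dQ = best_dq, Q = Q,
                                stringsAsFactors = FALSE)
    merges <- rbind(merges, c(bi, bj))
    # merge bj into bi
    w <- c(nbr[[bi]], nbr[[bj]])
    w <- tapply(w, names(w), sum)
    w <- w[!(names(w) %in% as.character(c(bi, bj)))]
    nbr[[bi]] <- stats::setNames(as.numeric(w), names(w))
    # redirect neighbors of bj (and bi) to bi
    for (nm in names(nbr[[bi]])) {
      jn <- as.integer(nm)
      nb <- nbr[[jn]]
      val <- getw(nb, as.character(bi)) + getw(nb, as.character(bj))
      nb <- nb[!(names(nb) %in% as.character(c(bi, bj)))]
      nb[as.character(bi)] <- val
      nbr[[jn]] <- nb
    }
    nbr[[bj]] <- numeric(0)
    a[bi] <- a[bi] + a[bj]
    active[bj] <- FALSE
    if (Q > best_Q + 1e-12) {
      best_Q <- Q
      best_step <- step
    }
    if (sum(active) == 1L) break
  }

  # replay merges up to the best cut to obtain the membership
  parent <- seq_len(N)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  lab <- nodes
  if (best_step > 0L) {
    for (s in seq_len(best_step)) {
      s_i <- merges[s, 1]; s_j <- merges[s, 2]
      parent[s_j] <- s_i
      lab[s_i] <- min(lab[s_i], lab[s_j])
    }
  }
  roots <- vapply(seq_len(N), find, integer(1))
  membership <- stats::setNames(lab[roots], nodes)
  q_final <- modularity_q(net, membership)
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), labelA = character(), labelB = character(),
               dQ = numeric(), Q = numeric(), stringsAsFactors = FALSE)
  structure(list(membership = membership, modularity = q_final,
                 n_communities = length(unique(membership)),
                 best_step = best_step, trace = trace_df, algorithm = "cnm"),
            class = "cnm_communities")
}

#' @export
print.cnm_communities <- function(x, ...) {
  cat(sprintf("Greedy modularity (CNM) clustering: %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Write the CNM merge trace as TSV
#' @param fit A `cnm_communities` object.
#' @param path Output path.
#' @export
write_merge_trace <- function(fit, path) write_tsv(fit$trace, path)
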