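#' Two-level map-equation codelength of a partition
#'
#' Expected per-step description length (in bits) of an unrecorded random
#' walk on a connected, undirected, unweighted graph under a two-level
#' (index + per-module) Huffman coding scheme. Stationary node visit rates
#' are `p_i = k_i / 2L` and the exit rate of module `m` is
#' `q_m = b_m / 2L` with `b_m` the number of boundary edges of `m`:
#' \deqn{L(M) = q\,H(Q) + \sum_m (p_m + q_m)\, H(P^m)}
#' where `q = sum_m q_m`, `H(Q)` is the entropy of the normalized exit rates
#' and `H(P^m)` the entropy of module `m`'s normalized visit-plus-exit rates
#' (`0 log 0 = 0`, logarithms base 2). For the one-module partition the
#' codelength equals the entropy of the visit-rate distribution exactly.
#'
#' @param net A connected igraph network.
#' @param part Partition covering the nodes of `net`.
#' @return Object of class `map_codelength`: list with `bits` (total),
#'   `index_bits` (index-codebook term) and `module_bits` (named vector of
#'   per-module codebook terms).
#' @export
map_equation <- function(net, part) {
  part <- as_partition(part, net)
  if (!igraph::is_connected(net)) {
    stopf("map equation requires a connected network (random walk must be ergodic)")
  }
  L <- igraph::ecount(net)
  if (L < 1) stopf("map equation requires at least one edge")
  k <- igraph::degree(net)
  p <- k / (2 * L)
  el <- igraph::as_edgelist(net)
  ca <- part[el[, 1]]
  cb <- part[el[, 2]]
  mods <- sort(unique(part))
  boundary <- ca != cb
  # boundary edge-endpoint counts per module
  b_m <- table(factor(c(ca[boundary], cb[boundary]), levels = mods))
  q_m <- stats::setNames(as.numeric(b_m) / (2 * L), mods)
  p_m <- stats::setNames(as.numeric(tapply(p[names(part)], part, sum)[mods]), mods)
  q <- sum(q_m)
  index_bits <- if (q > 0) q * log2(q) - sum(plogp(q_m)) else 0
  module_bits <- vapply(mods, function(m) {
    rates <- c(q_m[[m]], p[names(part)[part == m]])
    tot <- sum(rates)
    if (tot <= 0) return(0)
    tot * log2(tot) - sum(plogp(rates))
  }, numeric(1))
  names(module_bits) <- mods
  structure(list(bits = index_bits + sum(module_bits),
                 index_bits = index_bits,
                 module_bits = module_bits),
            class = "map_codelength")
}

#' @export
print.map_codelength <- function(x, ...) {
  cat(sprintf("Map-equation codelength: %.4f bits (index %.4f + modules %.4f) over %d modules\n",
              x$bits, x$index_bits, sum(x$module_bits), length(x$module_bits)))
  invisible(x)
}

# Closed-form codelength from module-level summaries, all in probability
# units: Q_sum = sum of exit rates, sq = sum plogp(exit rates),
# spq = sum plogp(exit + visit mass per module), spi = sum plogp(p_i) (const).
codelength_from_terms <- function(Q_sum, sq, spq, spi) {
  plogp(Q_sum) - 2 * sq + spq - spi
}

#' Map-equation community detection (infomap-style search)
#'
#' Minimizes the two-level map-equation codelength by repeated node-local
#' greedy moves (each node is tentatively moved to a neighboring module and
#' the move with the largest codelength decrease is kept), iterated to
#' convergence, followed by module-aggregation passes in which the coarse
#' module graph is searched the same way. The best of `n_trials` restarts
#' (node sweep orders drawn from the seeded RNG) is returned.
#'
#' @param net A connected igraph network.
#' @param seed Integer seed for reproducibility (optional).
#' @param n_trials Number of independent restarts (default 10).
#' @return Object of class `infomap_communities`: list with `membership`
#'   (named character vector; labels are arbitrary integers), `codelength`
#'   (a `map_codelength`, re-evaluated on the returned partition),
#'   `n_communities`, `n_trials`, and `algorithm = "infomap"`.
#' @export
infomap_cluster <- function(net, seed = NULL, n_trials = 10) {
  if (igraph::vcount(net) == 0) stopf("cannot cluster an empty network")
  if (!igraph::is_connected(net)) stopf("infomap search requires a connected network")
  L <- igraph::ecount(net)
  if (L < 1) stopf("clustering requires at least one edge")
  nodes <- igraph::V(net)$name
  N <- length(nodes)
  k <- as.numeric(igraph::degree(net))
  p_orig <- k / (2 * L)
  spi <- sum(plogp(p_orig))
  el0 <- igraph::as_edgelist(net, names = FALSE)

  best <- NULL
  with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      res <- infomap_once(N, el0, p_orig, spi, L)
      if (is.null(best) || res$bits < best$bits - 1e-12) best <- res
    }
  })
  membership <- stats::setNames(as.character(best$assign), nodes)
  # normalize labels to size-sorted ranks for stable output
  sizes <- sort(table(membership), decreasing = TRUE)
  relab <- stats::setNames(as.character(seq_along(sizes)), names(sizes))
  membership <- stats::setNames(relab[membership], nodes)
  structure(list(membership = membership,
                 codelength = map_equation(net, membership),
                 n_communities = length(unique(membership)),
                 n_trials = n_trials, algorithm = "infomap"),
            class = "infomap_communities")
}

#' @export
print.infomap_communities <- function(x, ...) {
  cat(sprintf("Map-equation (infomap-style) clustering: %d modules, codelength = %.4f bits\n",
              x$n_communities, x$codelength$bits))
  invisible(x)
}

# One full search trial: local moves + aggregation levels.
# Returns list(assign = module id per original node, bits = codelength).
infomap_once <- function(N, el0, p_orig, spi, L) {
  twoL <- 2 * L
  # current level state
  cn <- N                          # number of coarse nodes
  coarse_of <- seq_len(N)          # original node -> coarse node
  el <- el0                        # coarse edge list (with multiplicity)
  ew <- rep(1, nrow(el0))          # edge weights (original edge counts)
  pv <- p_orig                     # visit mass per coarse node
  selfw <- rep(0, N)               # self-loop weight per coarse node

  total_bits <- Inf
  repeat {
    st <- local_moves(cn, el, ew, pv, selfw, spi, twoL)
    if (st$bits < total_bits - 1e-10) {
      total_bits <- st$bits
    } else {
      break
    }
    # aggregate modules into coarse nodes
    mod <- st$mod
    mods <- sort(unique(mod))
    remap <- match(mod, mods)
    coarse_of <- remap[coarse_of]
    cn_new <- length(mods)
    pv_new <- numeric(cn_new)
    aggp <- tapply(pv, remap, sum)
    pv_new[as.integer(names(aggp))] <- as.numeric(aggp)
    pv <- pv_new
    ma <- remap[el[, 1]]
    mb <- remap[el[, 2]]
    selfw2 <- numeric(cn_new)
    agg <- tapply(selfw, remap, sum)
    selfw2[as.integer(names(agg))] <- as.numeric(agg)
    inter <- ma != mb
    if (any(ma == mb)) {
      agg2 <- tapply(ew[ma == mb], ma[ma == mb], sum)
      selfw2[as.integer(names(agg2))] <- selfw2[as.integer(names(agg2))] + as.numeric(agg2)
    }
    selfw <- selfw2
    if (any(inter)) {
      aa <- pmin(ma[inter], mb[inter])
      bb <- pmax(ma[inter], mb[inter])
      key <- paste(aa, bb)
      agg3 <- tapply(ew[inter], key, sum)
      kk <- strsplit(names(agg3), " ", fixed = TRUE)
      el <- cbind(vapply(kk, function(x) as.integer(x[1]), integer(1)),
                  vapply(kk, function(x) as.integer(x[2]), integer(1)))
      ew <- as.numeric(agg3)
    } else {
      el <- matrix(integer(0), ncol = 2)
      ew <- numeric(0)
    }
    cn <- cn_new
    if (cn == 1) break
  }
  list(assign = coarse_of, bits = total_bits)
}

# Greedy node-local move phase on one level. Each coarse node starts in its
# own module; sweeps in random order keep the single best codelength-reducing
# relocation per node until no move improves.
local_moves <- function(cn, el, ew, pv, selfw, spi, twoL) {
  # adjacency lists on the coarse graph (excluding self-loops)
  nbr_idx <- vector("list", cn)
  nbr_w <- vector("list", cn)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      a <- el[e, 1]; b <- el[e, 2]
      nbr_idx[[a]] <- c(nbr_idx[[a]], b); nbr_w[[a]] <- c(nbr_w[[a]], ew[e])
      nbr_idx[[b]] <- c(nbr_idx[[b]], a); nbr_w[[b]] <- c(nbr_w[[b]], ew[e])
    }
  }
  dv <- 2 * selfw + vapply(seq_len(cn), function(v) sum(nbr_w[[v]] %||% 0), numeric(1))
  extv <- dv - 2 * selfw                        # edges to other coarse nodes
  mod <- seq_len(cn)
  pm <- pv                                       # visit mass per module
  bm <- extv                                     # boundary edges per module
  Q_sum <- sum(bm) / twoL
  mt <- function(b, p) plogp(b / twoL + p) - 2 * plogp(b / twoL)
  # maintain sums: bits = plogp(Q_sum) + sum_m mt(bm, pm) - spi
  mtv <- mt(bm, pm)
  repeat {
    moved <- FALSE
    for (v in sample.int(cn)) {
      a <- mod[v]
      idx <- nbr_idx[[v]]
      if (is.null(idx)) next
      wmods <- tapply(nbr_w[[v]], mod[idx], sum)
      cand <- as.integer(names(wmods))
      w_va <- 0
      pos_a <- match(a, cand)
      if (!is.na(pos_a)) w_va <- as.numeric(wmods[pos_a])
      ba_new <- bm[a] - extv[v] + 2 * w_va
      pa_new <- pm[a] - pv[v]
      base_delta <- -mtv[a] + mt(ba_new, pa_new)
      best_delta <- 0
      best_b <- a
      for (ci in seq_along(cand)) {
        b <- cand[ci]
        if (b == a) next
        w_vb <- as.numeric(wmods[ci])
        bb_new <- bm[b] + extv[v] - 2 * w_vb
        pb_new <- pm[b] + pv[v]
        Q_new <- Q_sum + (ba_new + bb_new - bm[a] - bm[b]) / twoL
        delta <- plogp(Q_new) - plogp(Q_sum) + base_delta - mtv[b] + mt(bb_new, pb_new)
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_b <- b
        }
      }
      if (best_b != a) {
        b <- best_b
        w_vb <- as.numeric(wmods[match(b, cand)])
        bb_new <- bm[b] + extv[v] - 2 * w_vb
        pb_new <- pm[b] + pv[v]
        Q_sum <- Q_sum + (ba_new + bb_new - bm[a] - bm[b]) / twoL
        bm[a] <- ba_new; pm[a] <- pa_new; mtv[a] <- mt(ba_new, pa_new)
        bm[b] <- bb_new; pm[b] <- pb_new; mtv[b] <- mt(bb_new, pb_new)
        mod[v] <- b
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  bits <- plogp(Q_sum) + sum(mtv) - spi
  list(mod = mod, bits = bits)
}
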