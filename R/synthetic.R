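#' Ring of cliques benchmark graph
#'
#' `n_cliques` disjoint cliques of `clique_size` nodes joined into a cycle by
#' single bridge edges between designated contact nodes (node 1 of each
#' clique connects to node 2 of the next). This is the classic benchmark for
#' the resolution limit of modularity maximization: once the ring grows
#' beyond about `sqrt(2L)` cliques, merging neighboring cliques yields a
#' higher modularity than the natural per-clique partition, while the map
#' equation keeps resolving each clique.
#'
#' @param n_cliques Number of cliques (>= 3).
#' @param clique_size Clique size (>= 3).
#' @return List with `network` (igraph) and `truth` (a `planted_truth`:
#'   `micro` = `macro` = the per-clique partition, plus the parameters).
#' @export
ring_of_cliques <- function(n_cliques, clique_size) {
  if (n_cliques < 3 || clique_size < 3) stopf("need n_cliques >= 3 and clique_size >= 3")
  node_name <- function(ci, j) sprintf("c%03d_n%03d", ci, j)
  edges <- character(0)
  nodes <- character(0)
  from <- character(0); to <- character(0)
  for (ci in seq_len(n_cliques)) {
    ids <- vapply(seq_len(clique_size), function(j) node_name(ci, j), character(1))
    nodes <- c(nodes, ids)
    pr <- utils::combn(ids, 2)
    from <- c(from, pr[1, ]); to <- c(to, pr[2, ])
  }
  for (ci in seq_len(n_cliques)) {
    nxt <- if (ci == n_cliques) 1L else ci + 1L
    from <- c(from, node_name(ci, 1)); to <- c(to, node_name(nxt, 2))
  }
  g <- igraph::graph_from_data_frame(data.frame(from, to, stringsAsFactors = FALSE),
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  micro <- stats::setNames(rep(sprintf("clique%03d", seq_len(n_cliques)), each = clique_size), nodes)
  truth <- structure(list(micro = micro, macro = micro,
                          params = list(generator = "ring_of_cliques",
                                        n_cliques = n_cliques,
                                        clique_size = clique_size),
                          seed = NULL),
                     class = "planted_truth")
  list(network = g, truth = truth)
}

#' Two-scale planted-partition (hierarchical SBM) graph
#'
#' Bernoulli random graph with nested block structure: `n_macro` coarse
#' groups, each containing `micro_per_macro` fine modules of `micro_size`
#' nodes. Edge probabilities are `p_in_micro` within a fine module,
#' `p_in_macro` between fine modules of the same coarse group, and
#' `p_between` across coarse groups (the ordering
#' `p_in_micro > p_in_macro > p_between >= 0` is enforced). Disconnected
#' draws are regenerated (up to `max_retries`) so downstream random-walk
#' analyses are well defined. This emulates the two nested organization
#' scales on which greedy modularity and the map equation resolve different
#' granularities.
#'
#' In addition to the block structure, a small number of explicit
#' *interface* nodes can be planted (`n_interface`, default 12). Each
#' interface node is assigned a home fine module (its truth label), receives
#' `interface_home_links` links to random home-module members and one link
#' each to `interface_spread_links` distinct other fine modules. These nodes
#' emulate the high-participation "kinless" interface proteins observed in
#' real interaction networks, which a homogeneous block model cannot
#' produce: their participation is high (~0.85) while their total degree
#' stays below the hub threshold of their community.
#'
#' @param n_macro Number of coarse groups.
#' @param micro_per_macro Fine modules per coarse group.
#' @param micro_size Nodes per fine module.
#' @param p_in_micro,p_in_macro,p_between Edge probabilities (see above).
#' @param n_interface Number of planted interface nodes (0 disables).
#' @param interface_home_links Links from an interface node into its home
#'   module.
#' @param interface_spread_links Number of distinct foreign fine modules an
#'   interface node links into (one link each).
#' @param seed Integer seed (optional).
#' @param max_retries Regeneration attempts on disconnection.
#' @return List with `network` and `truth` (a `planted_truth` with `micro`
#'   and `macro` partitions; `micro` refines `macro` by construction;
#'   interface node ids in `$interface`).
#' @export
hierarchical_planted_graph <- function(n_macro = 4, micro_per_macro = 4,
                                       micro_size = 12, p_in_micro = 0.6,
                                       p_in_macro = 0.04, p_between = 0.003,
                                       n_interface = 12,
                                       interface_home_links = 3,
                                       interface_spread_links = 8,
                                       seed = NULL, max_retries = 50) {
  if (!(p_in_micro > p_in_macro && p_in_macro > p_between && p_between >= 0)) {
    stopf("require p_in_micro > p_in_macro > p_between >= 0")
  }
  n_micro <- n_macro * micro_per_macro
  macro_of_block <- rep(seq_len(n_macro), each = micro_per_macro)
  pref <- matrix(p_between, n_micro, n_micro)
  for (g in seq_len(n_macro)) {
    blk <- which(macro_of_block == g)
    pref[blk, blk] <- p_in_macro
  }
  diag(pref) <- p_in_micro
  sizes <- rep(micro_size, n_micro)
  nodes <- sprintf("g%02d_m%02d_n%03d",
                   rep(macro_of_block, times = sizes),
                   rep(seq_len(n_micro), times = sizes),
                   unlist(lapply(sizes, seq_len)))
  if (n_interface > 0 && interface_spread_links >= n_micro) {
    stopf("interface_spread_links must be smaller than the number of fine modules")
  }
  micro_block <- rep(seq_len(n_micro), times = sizes)
  out <- with_seed(seed, {
    found <- NULL
    for (try in seq_len(max_retries)) {
      cand <- igraph::sample_sbm(sum(sizes), pref.matrix = pref, block.sizes = sizes)
      igraph::V(cand)$name <- nodes
      iface_home <- integer(0)
      if (n_interface > 0) {
        # interface nodes: a home module plus single links spread across
        # distinct foreign fine modules
        iface_home <- rep_len(seq_len(n_micro), n_interface)
        iface_names <- sprintf("iface%02d", seq_len(n_interface))
        cand <- igraph::add_vertices(cand, n_interface, name = iface_names)
        ends <- character(0)
        for (i in seq_len(n_interface)) {
          home <- iface_home[i]
          home_members <- nodes[micro_block == home]
          # jitter the link counts so interface nodes blend into the overall
          # degree distribution instead of forming their own degree class
          n_home <- max(1, interface_home_links + sample(-1:1, 1))
          n_spread <- min(n_micro - 1,
                          max(2, interface_spread_links + sample(-2:2, 1)))
          targets <- sample(home_members, min(n_home, length(home_members)))
          foreign <- sample(setdiff(seq_len(n_micro), home), n_spread)
          targets <- c(targets, vapply(foreign, function(b) {
            sample(nodes[micro_block == b], 1)
          }, character(1)))
          ends <- c(ends, as.vector(rbind(iface_names[i], targets)))
        }
        cand <- igraph::add_edges(cand, ends)
      }
      if (igraph::is_connected(cand)) {
        found <- list(g = cand, iface_home = iface_home)
        break
      }
    }
    found
  })
  if (is.null(out)) stopf("could not draw a connected graph in %d attempts", max_retries)
  g <- out$g
  all_nodes <- igraph::V(g)$name
  block_of <- c(micro_block, out$iface_home)
  micro <- stats::setNames(sprintf("micro%02d", block_of), all_nodes)
  macro <- stats::setNames(sprintf("macro%02d", macro_of_block[block_of]), all_nodes)
  truth <- structure(list(micro = micro, macro = macro,
                          interface = grep("^iface", all_nodes, value = TRUE),
                          params = list(generator = "hierarchical_planted_graph",
                                        n_macro = n_macro,
                                        micro_per_macro = micro_per_macro,
                                        micro_size = micro_size,
                                        p_in_micro = p_in_micro,
                                        p_in_macro = p_in_macro,
                                        p_between = p_between,
                                        n_interface = n_interface,
                                        interface_home_links = interface_home_links,
                                        interface_spread_links = interface_spread_links),
                          seed = seed),
                     class = "planted_truth")
  truth$participation <- participation(g, micro)
  list(network = g, truth = truth)
}

#' Gene set planted at module interfaces with a degree bias
#'
#' Samples `size` nodes without replacement with weight proportional to
#' `exp(beta * P_i) * k_i^gamma`, where `P_i` is the participation
#' coefficient under `part`. `beta` tilts the set toward high-participation
#' interface ("kinless") nodes — emulating the reported 2-3 fold interface
#' enrichment of aging genes — and `gamma` adds the heavy-tailed degree bias
#' such phenotype sets display.
#'
#' @param net An igraph network.
#' @param part Partition used to compute participation.
#' @param size Set size.
#' @param beta Interface (participation) bias, >= 0.
#' @param gamma Degree bias, >= 0.
#' @param seed Integer seed (optional).
#' @return Character vector of node ids.
#' @export
planted_interface_geneset <- function(net, part, size, beta = 5, gamma = 1, seed = NULL) {
  if (beta < 0 || gamma < 0) stopf("beta and gamma must be >= 0")
  nodes <- igraph::V(net)$name
  if (size > length(nodes)) stopf("size exceeds the number of nodes")
  p <- participation(net, part)[nodes]
  k <- as.numeric(igraph::degree(net)[nodes])
  w <- exp(beta * p) * ifelse(k == 0 & gamma == 0, 1, k^gamma)
  with_seed(seed, sort(sample(nodes, size, prob = w)))
}

#' Module-aligned functional annotations
#'
#' Gives every fine (micro) module of a planted truth its own dedicated
#' functional class labels and annotates each member node with the full
#' class set of its module; with probability `noise` a node's classes are
#' replaced by those of a module drawn uniformly at random (so `noise = 1`
#' makes the annotations exactly independent of the modules, and
#' `noise = 0` gives a micro-truth BHI of exactly 1).
#'
#' @param truth A `planted_truth` (its `micro` partition is used).
#' @param n_classes_per_module Dedicated classes per module (default 1).
#' @param noise Corruption probability in `[0, 1]`.
#' @param seed Integer seed (optional).
#' @return An `annotation_map` (node -> classes).
#' @export
module_aligned_annotations <- function(truth, n_classes_per_module = 1,
                                       noise = 0, seed = NULL) {
  if (noise < 0 || noise > 1) stopf("noise must be in [0, 1]")
  micro <- as_partition(truth$micro)
  mods <- sort(unique(micro))
  classes_of <- stats::setNames(lapply(mods, function(m) {
    sprintf("class_%s_%02d", m, seq_len(n_classes_per_module))
  }), mods)
  nodes <- names(micro)
  ann <- with_seed(seed, {
    lapply(stats::setNames(nodes, nodes), function(nd) {
      m <- micro[[nd]]
      if (length(mods) > 1 && stats::runif(1) < noise) {
        m <- sample(mods, 1)
      }
      classes_of[[m]]
    })
  })
  structure(ann, class = "annotation_map")
}

#' Single degree-matched control gene set
#'
#' One realization of the degree-matched sampler used by
#' [degree_bootstrap_pvalue()], exposed as a generator: each reference gene
#' is replaced by a uniform draw from the pool of nodes with the same degree
#' (without replacement; exhausted pools widen geometrically).
#'
#' @param net An igraph network.
#' @param reference Character vector of reference node ids.
#' @param seed Integer seed (optional).
#' @return Character vector of control node ids (same size as `reference`).
#' @export
degree_matched_control_set <- function(net, reference, seed = NULL) {
  deg <- igraph::degree(net)
  reference <- intersect(unique(reference), names(deg))
  if (length(reference) == 0) stopf("reference set does not map to the network")
  ctrl <- with_seed(seed, sample_degree_matched(names(deg), as.numeric(deg),
                                                as.numeric(deg[reference])))
  if (isTRUE(attr(ctrl, "binned_fallback"))) {
    message("some exact-degree pools were exhausted; widened degree bins used")
  }
  sort(as.character(ctrl))
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("Planted truth (%s): %d nodes, %d micro / %d macro communities\n",
              x$params$generator %||% "?", length(x$micro),
              length(unique(x$micro)), length(unique(x$macro))))
  invisible(x)
}
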