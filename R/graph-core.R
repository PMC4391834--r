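#' Read an undirected simple network from an edge-list file
#'
#' Reads two-column tab/whitespace separated edge lists (`format = "tsv"`) or
#' three-column SIF files (`format = "sif"`, the middle interaction-type
#' column is ignored). Lines starting with `#` are comments. Duplicate edges
#' (including reversed duplicates) collapse to a single edge; self-loop lines
#' are dropped with a warning. Node identifiers are opaque strings.
#'
#' @param path Path to the file.
#' @param format Either `"tsv"` (2 columns) or `"sif"` (3 columns).
#' @return An undirected simple [igraph][igraph::graph] graph with named
#'   vertices.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\ta", "a\ta", "b\tc"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g); igraph::ecount(g)
#' @export
read_edge_list <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("edge-list file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  want <- if (format == "tsv") 2L else 3L
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  nfield <- lengths(parts)
  if (any(nfield != want)) {
    bad <- idx[which(nfield != want)[1]]
    stopf("malformed %s line %d in %s: expected %d fields, found %d",
          format, bad, path, want, nfield[which(nfield != want)[1]])
  }
  if (length(parts) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  m <- do.call(rbind, parts)
  from <- m[, 1]
  to <- m[, if (format == "tsv") 2 else 3]
  nodes <- sort(unique(c(from, to)))
  loops <- from == to
  if (any(loops)) {
    warnf("dropped %d self-loop line(s) in %s", sum(loops), path)
    from <- from[!loops]
    to <- to[!loops]
  }
  # canonical orientation so that reversed duplicates collapse
  a <- pmin(from, to)
  b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  edges <- cbind(a[!dup], b[!dup])
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g
}

#' Write a network as a two-column TSV edge list
#'
#' @param net An igraph network with named vertices.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  ord <- order(a, b)
  writeLines(paste(a[ord], b[ord], sep = "\t"), path)
  invisible(path)
}

#' Giant connected component
#'
#' Returns the induced subgraph on the largest connected component. If several
#' components tie for the largest size, the component containing the
#' lexicographically smallest node identifier among the tied components wins.
#'
#' @param net An igraph network with named vertices.
#' @return The induced subgraph on the giant component.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0) stopf("cannot take the giant component of an empty network")
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    reps <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1))
    best <- best[which(reps == min(reps))[1]]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Node degrees
#'
#' @param net An igraph network.
#' @return Named integer vector of degrees (number of direct neighbors).
#' @export
node_degrees <- function(net) {
  igraph::degree(net)
}

#' Local clustering coefficient
#'
#' Fraction of realized edges among a node's neighbors,
#' `(edges among neighbors) / (k(k-1)/2)`. Nodes of degree < 2, for which the
#' ratio is undefined, are assigned 0 by convention so the per-node table
#' stays total.
#'
#' @param net An igraph network.
#' @param nodes Optional character vector of node ids (default: all nodes).
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, nodes = NULL) {
  all_nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- all_nodes
  unknown <- setdiff(nodes, all_nodes)
  if (length(unknown)) stopf("unknown node(s): %s", paste(unknown, collapse = ", "))
  cc <- igraph::transitivity(net, type = "local", vids = nodes, isolates = "zero")
  stats::setNames(cc, nodes)
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized betweenness: each unordered node pair is counted once,
#' endpoints are excluded, and multiple equal-length shortest paths contribute
#' fractionally (Brandes accumulation). Only the rank order is used downstream
#' (ROC comparison of topological predictors), so no normalization is applied.
#'
#' @param net An igraph network.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' Bridging coefficient and bridging centrality
#'
#' The bridging coefficient of node `v` is
#' `bc(v) = (1/k(v)) / sum_{i in N(v)} 1/k(i)` and the bridging centrality is
#' the product `BC(v) = be(v) * bc(v)` with `be` the (unnormalized)
#' betweenness. It scores how well a node sits between well-connected
#' regions. Degree-0 nodes have an undefined bridging coefficient and are
#' stored as 0 with a warning.
#'
#' @param net An igraph network.
#' @return Data frame with columns `node`, `bridging_coefficient`,
#'   `bridging_centrality`.
#' @export
bridging_centrality <- function(net) {
  k <- igraph::degree(net)
  be <- betweenness_centrality(net)
  nodes <- igraph::V(net)$name
  bc <- numeric(length(nodes))
  names(bc) <- nodes
  if (any(k == 0)) warnf("%d degree-0 node(s): bridging coefficient stored as 0", sum(k == 0))
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  for (i in seq_along(nodes)) {
    if (k[i] == 0) next
    nb <- nodes[as.integer(adj[[i]])]
    bc[i] <- (1 / k[i]) / sum(1 / k[nb])
  }
  data.frame(node = nodes, bridging_coefficient = unname(bc),
             bridging_centrality = unname(be[nodes] * bc),
             stringsAsFactors = FALSE)
}

#' Per-node centrality table
#'
#' Assembles degree, local clustering, betweenness, bridging coefficient and
#' bridging centrality into one table (one row per node).
#'
#' @param net An igraph network.
#' @return Data frame with columns `node`, `degree`, `clustering`,
#'   `betweenness`, `bridging_coefficient`, `bridging_centrality`.
#' @export
centrality_table <- function(net) {
  nodes <- igraph::V(net)$name
  br <- bridging_centrality(net)
  data.frame(
    node = nodes,
    degree = unname(igraph::degree(net)[nodes]),
    clustering = unname(clustering_coefficient(net)[nodes]),
    betweenness = unname(betweenness_centrality(net)[nodes]),
    bridging_coefficient = br$bridging_coefficient[match(nodes, br$node)],
    bridging_centrality = br$bridging_centrality[match(nodes, br$node)],
    stringsAsFactors = FALSE
  )
}

#' @rdname centrality_table
#' @param tab Centrality table.
#' @param path Output TSV path.
#' @export
write_centrality_table <- function(tab, path) write_tsv(tab, path)
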