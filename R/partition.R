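#' Coerce to a node partition
#'
#' A partition is represented throughout the package as a named character
#' vector mapping every node identifier to an (opaque) community label.
#' Community labels are arbitrary: all comparisons performed by the package
#' are label-invariant.
#'
#' @param x A named vector (node -> label), or a community-detection result
#'   produced by [cnm_cluster()] / [infomap_cluster()] (its `membership`
#'   element is used), or an igraph `communities` object.
#' @param net Optional [igraph][igraph::graph] network; when supplied, the
#'   partition is checked to cover exactly the nodes of `net`.
#' @return Named character vector of community labels.
#' @export
as_partition <- function(x, net = NULL) {
  if (inherits(x, "communities")) {
    part <- as.character(igraph::membership(x))
    names(part) <- names(igraph::membership(x))
  } else if (is.list(x) && !is.null(x$membership)) {
    part <- as.character(x$membership)
    names(part) <- names(x$membership)
  } else if (is_named_vector(x)) {
    part <- stats::setNames(as.character(x), names(x))
  } else {
    stopf("cannot interpret object of class '%s' as a partition", class(x)[1])
  }
  if (anyNA(part)) stopf("partition contains missing community labels")
  if (anyDuplicated(names(part))) stopf("partition assigns some nodes twice")
  if (!is.null(net)) check_partition(net, part)
  part
}

# Validate that a partition covers exactly the node set of the network.
check_partition <- function(net, part) {
  nodes <- igraph::V(net)$name
  if (!setequal(nodes, names(part)) || length(part) != length(nodes)) {
    stopf(
      "partition does not cover the network: %d nodes vs %d labelled ids",
      length(nodes), length(part)
    )
  }
  invisible(TRUE)
}

#' List the communities of a partition
#'
#' @param part Partition (see [as_partition()]).
#' @return Named list of character vectors, one per community label.
#' @export
partition_communities <- function(part) {
  part <- as_partition(part)
  split(names(part), part)
}

#' Number of communities in a partition
#' @param part Partition.
#' @return Integer count of distinct community labels.
#' @export
n_communities <- function(part) {
  length(unique(as_partition(part)))
}

#' Read / write a partition as two-column TSV
#'
#' The on-disk format is a tab-separated table with columns `node` and
#' `community` (header included, `#` comment lines ignored on read).
#'
#' @param part Partition to write.
#' @param path File path.
#' @return `write_partition` returns the path invisibly; `read_partition`
#'   returns a named character vector.
#' @export
write_partition <- function(part, path) {
  part <- as_partition(part)
  ord <- order(names(part))
  write_tsv(data.frame(node = names(part)[ord], community = unname(part)[ord],
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character")
  if (!all(c("node", "community") %in% names(df))) {
    stopf("partition file %s lacks node/community columns", path)
  }
  stats::setNames(df$community, df$node)
}
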