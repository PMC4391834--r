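#' Within-module degree z-score
#'
#' For each node, `Z_i = (k_i - mean(k_C)) / sd(k_C)` where the mean and
#' standard deviation are taken over the degrees of all nodes in the node's
#' own community. The population (divide-by-n) standard deviation is used;
#' if a community's degrees are constant (`sd = 0`), its members get `Z = 0`
#' by convention.
#'
#' @param net An igraph network.
#' @param part Partition covering the nodes.
#' @return Named numeric vector of Z values.
#' @export
within_module_degree_z <- function(net, part) {
  part <- as_partition(part, net)
  k <- igraph::degree(net)[names(part)]
  mu <- tapply(k, part, mean)
  pop_sd <- tapply(k, part, function(x) sqrt(mean((x - mean(x))^2)))
  z <- (k - mu[part]) / pop_sd[part]
  z[!is.finite(z)] <- 0
  stats::setNames(as.numeric(z), names(part))
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_C (k_iC / k_i)^2` where `k_iC` counts node i's links into
#' community C (the sum runs over all communities, and
#' `sum_C k_iC = k_i`). P is 0 when all links stay inside the node's own
#' community and approaches 1 when links are spread evenly over many
#' communities. Isolated nodes get `P = 0` by convention.
#'
#' @param net An igraph network.
#' @param part Partition covering the nodes.
#' @return Named numeric vector of P values in `[0, 1)`.
#' @export
participation <- function(net, part) {
  part <- as_partition(part, net)
  nodes <- igraph::V(net)$name
  adj <- igraph::as_adj_list(net)
  p <- vapply(seq_along(nodes), function(i) {
    nb <- nodes[as.integer(adj[[i]])]
    k <- length(nb)
    if (k == 0) return(0)
    shares <- table(part[nb]) / k
    1 - sum(shares^2)
  }, numeric(1))
  stats::setNames(p, nodes)[names(part)]
}

#' Universal cartographic role assignment
#'
#' Guimera-Amaral role classification on the (Z, P) plane. Nodes with
#' `Z >= z_hub` (default 2.5) are module hubs. Non-hubs: R1 ultra-peripheral
#' (`P < p_r1`, default 0.05, operationalizing "P ~ 0"), R2 peripheral
#' (`P < 0.625`), R3 connector (`P < 0.8`), R4 kinless (`P >= 0.8`). Hubs:
#' R5 provincial (`P < 0.3`), R6 connector (`P < 0.75`), R7 kinless
#' (`P >= 0.75`). Intervals are left-closed/right-open except the top
#' category.
#'
#' @param z,p Numeric vectors (recycled to common length) of within-module
#'   degree and participation.
#' @param z_hub Hub threshold on Z (inclusive).
#' @param p_r1 R1/R2 boundary on P.
#' @return Character vector of roles `"R1".."R7"`.
#' @export
assign_role <- function(z, p, z_hub = 2.5, p_r1 = 0.05) {
  n <- max(length(z), length(p))
  z <- rep_len(z, n)
  p <- rep_len(p, n)
  if (any(p < 0 | p >= 1)) stopf("participation values must lie in [0, 1)")
  hub <- z >= z_hub
  role <- character(n)
  role[!hub & p < p_r1] <- "R1"
  role[!hub & p >= p_r1 & p < 0.625] <- "R2"
  role[!hub & p >= 0.625 & p < 0.8] <- "R3"
  role[!hub & p >= 0.8] <- "R4"
  role[hub & p < 0.3] <- "R5"
  role[hub & p >= 0.3 & p < 0.75] <- "R6"
  role[hub & p >= 0.75] <- "R7"
  role
}

#' Cartographic table of a partitioned network
#'
#' Combines degree, community label, within-module degree Z, participation P
#' and the universal role of every node into one table. Role counts (the
#' distribution of nodes over R1..R7) are attached as the `role_counts`
#' attribute.
#'
#' @inheritParams assign_role
#' @param net An igraph network.
#' @param part Partition covering the nodes.
#' @return Data frame of class `cartography_table` with columns `node`,
#'   `community`, `degree`, `z`, `p`, `role`, `is_hub`.
#' @export
cartography_table <- function(net, part, z_hub = 2.5, p_r1 = 0.05) {
  part <- as_partition(part, net)
  nodes <- igraph::V(net)$name
  z <- within_module_degree_z(net, part)
  p <- participation(net, part)
  role <- assign_role(z[nodes], p[nodes], z_hub = z_hub, p_r1 = p_r1)
  out <- data.frame(node = nodes,
                    community = unname(part[nodes]),
                    degree = unname(igraph::degree(net)[nodes]),
                    z = unname(z[nodes]),
                    p = unname(p[nodes]),
                    role = role,
                    is_hub = z[nodes] >= z_hub,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "role_counts") <- role_counts(out)
  attr(out, "params") <- list(z_hub = z_hub, p_r1 = p_r1, sd = "population")
  class(out) <- c("cartography_table", "data.frame")
  out
}

#' Role counts of a cartography table
#' @param carto A [cartography_table()].
#' @return Named integer vector over roles R1..R7.
#' @export
role_counts <- function(carto) {
  tab <- table(factor(carto$role, levels = paste0("R", 1:7)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Two-dimensional (Z, P) histogram
#'
#' Plain binned counts over the Z-P plane, the exportable counterpart of the
#' usual kernel-density cartography plots.
#'
#' @param carto A [cartography_table()].
#' @param z_breaks,p_breaks Break points for binning.
#' @return Matrix of counts (rows: Z bins, columns: P bins).
#' @export
zp_histogram <- function(carto, z_breaks = seq(-3, 8, by = 0.5),
                         p_breaks = seq(0, 1, by = 0.05)) {
  z <- pmin(pmax(carto$z, min(z_breaks)), max(z_breaks))
  p <- pmin(pmax(carto$p, min(p_breaks)), max(p_breaks) - 1e-9)
  table(cut(z, z_breaks, include.lowest = TRUE),
        cut(p, p_breaks, include.lowest = TRUE))
}

#' @rdname cartography_table
#' @param carto Cartography table.
#' @param path Output TSV path.
#' @export
write_cartography_table <- function(carto, path) {
  write_tsv(as.data.frame(carto), path)
}
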