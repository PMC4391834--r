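#' One-sided Fisher enrichment p-value
#'
#' Probability, under the hypergeometric null, of drawing at least `overlap`
#' category members in a sample of `set_size` from a background of
#' `background` nodes of which `category_size` are in the category. This is
#' the one-sided (enrichment) Fisher exact test p-value for the 2x2 table.
#'
#' @param overlap Observed gene-set nodes in the category.
#' @param category_size Nodes in the category.
#' @param set_size Gene-set size.
#' @param background Total background size.
#' @return P-value in `(0, 1]`.
#' @export
fisher_enrichment_p <- function(overlap, category_size, set_size, background) {
  stats::phyper(overlap - 1, category_size, background - category_size,
                set_size, lower.tail = FALSE)
}

#' Role-wise Fisher enrichment of a gene set
#'
#' For each cartographic role R1..R7, tests enrichment of the gene set in
#' the role with the one-sided Fisher exact test on the 2x2 table of
#' role-by-set membership, and adjusts across the 7 roles with
#' Benjamini-Hochberg.
#'
#' @param carto A [cartography_table()].
#' @param gene_set Character vector of node ids (unmapped ids are dropped
#'   with a message).
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`
#'   (via [stats::fisher.test()]).
#' @param p_adjust_n Family size for the BH correction (default 7, the roles
#'   of one partition; use 14 to correct across two partitions jointly).
#' @return Data frame of class `enrichment_table` with one row per role:
#'   `role`, `n_nodes`, `n_set`, `odds_ratio`, `p_raw`, `p_adj`, `p_boot`
#'   (NA until filled by [degree_bootstrap_pvalue()]).
#' @export
fisher_role_enrichment <- function(carto, gene_set,
                                   alternative = c("greater", "two.sided"),
                                   p_adjust_n = 7) {
  alternative <- match.arg(alternative)
  roles <- paste0("R", 1:7)
  gene_set <- unique(gene_set)
  mapped <- intersect(gene_set, carto$node)
  if (length(mapped) < length(gene_set)) {
    message(sprintf("%d of %d gene-set ids mapped to the network", length(mapped), length(gene_set)))
  }
  if (length(mapped) == 0) warnf("empty (or unmapped) gene set: all p-values are 1")
  N <- nrow(carto)
  n_set <- length(mapped)
  in_set <- carto$node %in% mapped
  out <- data.frame(role = roles, n_nodes = 0L, n_set = 0L,
                    odds_ratio = NA_real_, p_raw = 1, p_adj = 1,
                    p_boot = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(roles)) {
    in_role <- carto$role == roles[i]
    a <- sum(in_role & in_set)
    out$n_nodes[i] <- sum(in_role)
    out$n_set[i] <- a
    b <- sum(in_role) - a
    c <- n_set - a
    d <- N - sum(in_role) - c
    out$odds_ratio[i] <- (a * d) / (b * c)
    if (n_set == 0) next
    out$p_raw[i] <- if (alternative == "greater") {
      fisher_enrichment_p(a, sum(in_role), n_set, N)
    } else {
      stats::fisher.test(matrix(c(a, b, c, d), 2), alternative = "two.sided")$p.value
    }
  }
  out$p_adj <- pmin(1, stats::p.adjust(out$p_raw, method = "BH", n = max(p_adjust_n, 7)))
  attr(out, "n_set") <- n_set
  attr(out, "background") <- N
  attr(out, "alternative") <- alternative
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# Degree-matched sampling of one control set. Pools are exact-degree node
# pools; when a pool is exhausted the window widens geometrically (factor
# sqrt(2)) around the target degree until enough unused nodes exist.
sample_degree_matched <- function(node_names, node_degrees, ref_degrees) {
  taken <- character(0)
  picked <- character(0)
  fallback <- FALSE
  for (d in sort(ref_degrees, decreasing = TRUE)) {
    lo <- d; hi <- d
    repeat {
      pool <- node_names[node_degrees >= lo & node_degrees <= hi]
      pool <- setdiff(pool, taken)
      if (length(pool) >= 1) break
      if (lo <= 0 && hi > max(node_degrees)) stopf("degree pools exhausted")
      lo <- floor(lo / sqrt(2)); hi <- ceiling(hi * sqrt(2))
      fallback <- TRUE
    }
    if (lo != d || hi != d) fallback <- TRUE
    pick <- pool[sample.int(length(pool), 1L)]
    taken <- c(taken, pick)
    picked <- c(picked, pick)
  }
  attr(picked, "binned_fallback") <- fallback
  picked
}

#' Degree-controlled bootstrap p-values for role enrichment
#'
#' De-convolves the degree signal from role enrichment: `n` random control
#' gene sets are drawn with the same degree distribution as the query set
#' (each gene replaced by a uniform draw from the pool of equal-degree
#' nodes, without replacement within a realization; exhausted pools widen
#' geometrically by factor sqrt(2)). The bootstrap p-value of a role is the
#' `(1 + r) / (n + 1)` fraction of realizations whose role count reaches the
#' observed one, so p-values are never exactly zero.
#'
#' @param net An igraph network (for node degrees).
#' @param carto A [cartography_table()] of the same network.
#' @param gene_set Character vector of node ids.
#' @param n Number of bootstrap realizations (default 1000).
#' @param seed Integer seed (optional).
#' @return Data frame with one row per role: `role`, `observed`,
#'   `boot_mean`, `p_boot`, `p_boot_adj` (BH across the 7 roles).
#' @export
degree_bootstrap_pvalue <- function(net, carto, gene_set, n = 1000, seed = NULL) {
  if (n < 1) stopf("need at least one bootstrap realization")
  roles <- paste0("R", 1:7)
  mapped <- intersect(unique(gene_set), carto$node)
  if (length(mapped) == 0) stopf("gene set does not map to the network")
  deg <- igraph::degree(net)
  role_of <- stats::setNames(carto$role, carto$node)
  obs <- table(factor(role_of[mapped], levels = roles))
  ref_degrees <- as.numeric(deg[mapped])
  node_names <- names(deg)
  node_degrees <- as.numeric(deg)
  counts <- matrix(0L, nrow = n, ncol = 7, dimnames = list(NULL, roles))
  n_fallback <- 0L
  with_seed(seed, {
    for (r in seq_len(n)) {
      ctrl <- sample_degree_matched(node_names, node_degrees, ref_degrees)
      if (isTRUE(attr(ctrl, "binned_fallback"))) n_fallback <- n_fallback + 1L
      counts[r, ] <- as.integer(table(factor(role_of[ctrl], levels = roles)))
    }
  })
  if (n_fallback > 0) {
    message(sprintf("degree pools exhausted in %d/%d realizations; used widened degree bins", n_fallback, n))
  }
  p_boot <- vapply(seq_len(7), function(i) {
    (1 + sum(counts[, i] >= as.integer(obs[i]))) / (n + 1)
  }, numeric(1))
  out <- data.frame(role = roles,
                    observed = as.integer(obs),
                    boot_mean = colMeans(counts),
                    p_boot = p_boot,
                    p_boot_adj = pmin(1, stats::p.adjust(p_boot, method = "BH")),
                    stringsAsFactors = FALSE)
  attr(out, "realization_counts") <- counts
  out
}

#' Drop the most-connected members of a gene set
#'
#' Removes the `ceiling(fraction * |set|)` members with the highest degree.
#' Ties at the cut are resolved deterministically: among equal degrees,
#' members with lexicographically smaller ids are removed first (higher ids
#' are the last to go).
#'
#' @param gene_set Character vector of node ids.
#' @param net An igraph network containing the members.
#' @param fraction Fraction to remove, in `[0, 1)` (default 0.10).
#' @return The truncated gene set.
#' @export
truncate_top_degree <- function(gene_set, net, fraction = 0.10) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stopf("empty gene set")
  if (fraction < 0 || fraction >= 1) stopf("fraction must be in [0, 1)")
  r <- ceiling(fraction * length(gene_set))
  if (r == 0) return(gene_set)
  deg <- igraph::degree(net)[gene_set]
  ord <- order(-deg, gene_set)
  sort(gene_set[ord][-seq_len(r)])
}

#' Degree-bounded node subset
#'
#' Nodes whose degree does not exceed the given percentile of the network's
#' degree distribution (lower nearest-rank percentile), used to evaluate
#' predictors on mid/low-connectivity nodes only.
#'
#' @param net An igraph network.
#' @param percentile Percentile in `(0, 100)` (default 90).
#' @return Character vector of node ids.
#' @export
degree_bounded_nodes <- function(net, percentile = 90) {
  if (percentile <= 0 || percentile >= 100) stopf("percentile must be in (0, 100)")
  deg <- igraph::degree(net)
  s <- sort(as.numeric(deg))
  idx <- max(1L, floor(percentile / 100 * length(s)))
  cutoff <- s[idx]
  names(deg)[deg <= cutoff]
}

#' ROC curve and AUC of a node score against a gene set
#'
#' Threshold sweep over the score (higher = more positive) with tied scores
#' collapsed into single curve segments; the AUC equals the Mann-Whitney
#' probability estimate (rank-based, tie-aware).
#'
#' @param scores Named numeric vector of node scores.
#' @param positives Character vector of positive node ids.
#' @param eval_nodes Optional node subset to evaluate on (default: all
#'   scored nodes). Must contain at least one positive and one negative.
#' @return List of class `roc_result` with `curve` (data frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, positives, eval_nodes = NULL) {
  if (is.null(eval_nodes)) eval_nodes <- names(scores)
  eval_nodes <- intersect(eval_nodes, names(scores))
  y <- eval_nodes %in% positives
  if (!any(y) || all(y)) stopf("evaluation set needs at least one positive and one negative")
  s <- as.numeric(scores[eval_nodes])
  npos <- sum(y)
  nneg <- sum(!y)
  r <- rank(s)
  auc <- (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y & s >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!y & s >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / nneg),
                      tpr = c(0, tp / npos))
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d thresholds)\n", x$auc, nrow(x$curve) - 1))
  invisible(x)
}

#' DeLong test for paired AUC difference
#'
#' Compares the AUCs of two scores evaluated on the same nodes against the
#' same positive set, using the DeLong placement-based covariance estimate
#' of the paired AUC difference and a normal approximation for the p-value.
#' Identical score vectors give `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Named numeric score vectors (same nodes).
#' @param positives Character vector of positive node ids.
#' @param eval_nodes Optional evaluation subset.
#' @return List of class `delong_result`: `auc_a`, `auc_b`, `z`, `p`
#'   (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, positives, eval_nodes = NULL) {
  if (is.null(eval_nodes)) eval_nodes <- intersect(names(scores_a), names(scores_b))
  eval_nodes <- Reduce(intersect, list(eval_nodes, names(scores_a), names(scores_b)))
  y <- eval_nodes %in% positives
  if (!any(y) || all(y)) stopf("evaluation set needs at least one positive and one negative")
  placements <- function(s) {
    x <- s[y]          # positives
    yn <- s[!y]        # negatives
    m <- length(x); nn <- length(yn)
    psi <- outer(x, yn, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  pa <- placements(as.numeric(scores_a[eval_nodes]))
  pb <- placements(as.numeric(scores_b[eval_nodes]))
  m <- sum(y); nn <- sum(!y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / nn
  d <- pa$auc - pb$auc
  if (v <= 0 || !is.finite(v)) {
    z <- 0
    p <- 1
    if (abs(d) > 0) { z <- sign(d) * Inf; p <- 0 }
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: AUC_A = %.4f, AUC_B = %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Read a gene set from a one-id-per-line text file
#' @param path File path (`#` comments and blank lines skipped).
#' @return Character vector of ids.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unique(trimws(lines[!grepl("^\\s*(#|$)", lines)]))
}
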