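#' Read gene sets / annotations in GMT format
#'
#' Each GMT line is `set-name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate memberships are dropped. Lines starting with `#` are skipped.
#'
#' @param path Path to the GMT file.
#' @return Object of class `gmt`: a named list of character vectors (one per
#'   set), with set descriptions in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  sets <- list()
  desc <- character()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line %d in %s: need name, description and >= 1 member", i, path)
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  structure(sets, descriptions = desc, class = "gmt")
}

#' Invert set-oriented annotations to a node -> classes map
#'
#' @param x A `gmt` object (or plain named list of member vectors).
#' @return Object of class `annotation_map`: named list mapping each node id
#'   to the character vector of functional classes it belongs to.
#' @export
as_annotation_map <- function(x) {
  if (inherits(x, "annotation_map")) return(x)
  pairs <- data.frame(node = unlist(unname(x), use.names = FALSE),
                      class = rep(names(x), lengths(x)),
                      stringsAsFactors = FALSE)
  out <- lapply(split(pairs$class, pairs$node), unique)
  structure(out, class = "annotation_map")
}

#' Biological homogeneity index
#'
#' Average, over communities, of the fraction of (ordered) pairs of annotated
#' community members that share at least one functional class:
#' \deqn{BHI = \frac{1}{K}\sum_k \frac{1}{n_k(n_k-1)}
#'       \sum_{i \ne j \in C_k} 1\{\mathrm{classes}(i)\cap\mathrm{classes}(j)\ne\emptyset\}}
#' where `n_k` counts the annotated nodes of community `k` and `K` counts
#' communities with `n_k >= 2`. Unannotated nodes are excluded from the pair
#' counting; communities with fewer than 2 annotated members do not
#' contribute.
#'
#' @param part Partition (named node -> community vector).
#' @param ann Annotations: an `annotation_map`, a `gmt` object, or a named
#'   list node -> classes.
#' @return BHI in `[0, 1]`.
#' @export
bhi <- function(part, ann) {
  part <- as_partition(part)
  ann <- as_annotation_map(ann)
  annotated <- intersect(names(part), names(ann)[lengths(ann) > 0])
  comms <- split(annotated, part[annotated])
  comms <- comms[lengths(comms) >= 2]
  if (length(comms) == 0) stopf("no community has >= 2 annotated nodes")
  classes <- sort(unique(unlist(ann[annotated], use.names = FALSE)))
  mean(vapply(comms, function(members) {
    m <- matrix(0L, nrow = length(members), ncol = length(classes))
    for (i in seq_along(members)) {
      m[i, match(ann[[members[i]]], classes)] <- 1L
    }
    share <- tcrossprod(m) > 0
    n <- length(members)
    (sum(share) - sum(diag(share))) / (n * (n - 1))
  }, numeric(1)))
}

#' Label-shuffle null for the BHI of a nested partition
#'
#' Within each community of a coarse `parent` partition, the labels of the
#' nested `fine` partition are permuted uniformly among that community's
#' nodes (preserving each fine-label multiset), and the BHI of the permuted
#' fine partition is recorded. This tests whether the fine partition's
#' biological homogeneity exceeds what its community-size profile alone
#' would produce: the null mean reproduces the BHI of the structure-less
#' parent community.
#'
#' Nodes whose fine community spans several parent communities (i.e. where
#' `fine` does not refine `parent`) are excluded with a warning.
#'
#' @param parent Coarse partition.
#' @param fine Fine partition (a refinement of `parent` on the evaluated
#'   nodes).
#' @param ann Annotations (see [bhi()]).
#' @param n Number of shuffle realizations (default 1000).
#' @param seed Integer seed (optional).
#' @return Object of class `bhi_null`: list with `per_community` (data frame
#'   with observed fine BHI, parent-cluster BHI, null mean/sd and empirical
#'   p per parent community) and `pooled` (the same for the pooled fine
#'   partition, plus the raw null sample). Empirical p-values use the
#'   `(1 + r) / (n + 1)` estimator of the fraction of null values >= the
#'   observed one.
#' @export
bhi_shuffle_null <- function(parent, fine, ann, n = 1000, seed = NULL) {
  if (n < 1) stopf("need at least one shuffle realization")
  parent <- as_partition(parent)
  fine <- as_partition(fine)
  ann <- as_annotation_map(ann)
  nodes <- intersect(names(parent), names(fine))
  # refinement check at node level
  span <- tapply(parent[nodes], fine[nodes], function(x) length(unique(x)))
  bad_fine <- names(span)[span > 1]
  if (length(bad_fine)) {
    drop <- nodes[fine[nodes] %in% bad_fine]
    warnf("excluding %d node(s) whose fine community spans several parent communities", length(drop))
    nodes <- setdiff(nodes, drop)
  }
  parent <- parent[nodes]
  fine <- fine[nodes]

  bhi_safe <- function(part) tryCatch(bhi(part, ann), error = function(e) NA_real_)
  per_parent_nodes <- split(nodes, parent[nodes])

  observed <- vapply(per_parent_nodes, function(ns) bhi_safe(fine[ns]), numeric(1))
  parent_bhi <- vapply(names(per_parent_nodes), function(pc) {
    bhi_safe(stats::setNames(rep(pc, length(per_parent_nodes[[pc]])), per_parent_nodes[[pc]]))
  }, numeric(1))
  pooled_obs <- bhi_safe(fine)

  null_per <- matrix(NA_real_, nrow = n, ncol = length(per_parent_nodes),
                     dimnames = list(NULL, names(per_parent_nodes)))
  null_pooled <- numeric(n)
  with_seed(seed, {
    for (r in seq_len(n)) {
      shuffled <- fine
      for (ns in per_parent_nodes) {
        shuffled[ns] <- fine[sample(ns)]
      }
      for (pc in names(per_parent_nodes)) {
        null_per[r, pc] <- bhi_safe(shuffled[per_parent_nodes[[pc]]])
      }
      null_pooled[r] <- bhi_safe(shuffled)
    }
  })
  emp_p <- function(obs, null) {
    if (is.na(obs)) return(NA_real_)
    (1 + sum(null >= obs, na.rm = TRUE)) / (sum(!is.na(null)) + 1)
  }
  per_community <- data.frame(
    parent = names(per_parent_nodes),
    n_nodes = lengths(per_parent_nodes),
    bhi_fine = unname(observed),
    bhi_parent = unname(parent_bhi),
    null_mean = apply(null_per, 2, mean, na.rm = TRUE),
    null_sd = apply(null_per, 2, stats::sd, na.rm = TRUE),
    p_emp = vapply(names(per_parent_nodes),
                   function(pc) emp_p(observed[[pc]], null_per[, pc]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_community) <- NULL
  structure(list(per_community = per_community,
                 pooled = list(observed = pooled_obs,
                               null = null_pooled,
                               null_mean = mean(null_pooled, na.rm = TRUE),
                               null_sd = stats::sd(null_pooled, na.rm = TRUE),
                               p_emp = emp_p(pooled_obs, null_pooled)),
                 n = n, seed = seed),
            class = "bhi_null")
}

#' @export
print.bhi_null <- function(x, ...) {
  cat(sprintf("BHI shuffle null (%d realizations): observed %.4f, null %.4f +/- %.4f, p = %.4g\n",
              x$n, x$pooled$observed, x$pooled$null_mean, x$pooled$null_sd, x$pooled$p_emp))
  invisible(x)
}
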