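#' Read a pipeline run configuration
#'
#' Configurations are YAML (or JSON) files with blocks `network`,
#' `gene_set`, `annotations`, `settings`, plus a master `seed` and an
#' optional `output_dir`. See [run_full_analysis()] for the recognized
#' fields; missing settings fall back to defaults.
#'
#' @param path Path to a YAML/JSON config file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

default_settings <- function() {
  list(infomap_trials = 10,
       rewire_ensemble = 1000,
       swaps_per_edge = 10,
       bhi_shuffle_n = 1000,
       bootstrap_n = 1000,
       roc_percentile = 90,
       truncate_fraction = 0.10,
       p_adjust_n = 7,
       z_hub = 2.5,
       p_r1 = 0.05)
}

# Deterministic per-stage seed derivation from the master seed, kept within
# 32-bit integer range.
stage_seed <- function(master, stage) {
  stages <- c("generate", "infomap", "rewire", "bhi", "geneset", "annotations",
              "bootstrap_cnm", "bootstrap_infomap",
              "bootstrap_cnm_trunc", "bootstrap_infomap_trunc")
  i <- match(stage, stages)
  if (is.na(i)) stopf("unknown pipeline stage '%s'", stage)
  as.integer((as.numeric(master) * 97 + i * 1000003) %% 2147483647)
}

build_network <- function(cfg, seed) {
  nb <- cfg$network
  if (!is.null(nb$edge_list)) {
    net <- read_edge_list(nb$edge_list, format = nb$format %||% "tsv")
    return(list(network = net, truth = NULL))
  }
  syn <- nb$synthetic
  if (is.null(syn)) stopf("config needs network$edge_list or network$synthetic")
  args <- syn[setdiff(names(syn), "generator")]
  if (identical(syn$generator, "ring_of_cliques")) {
    do.call(ring_of_cliques, args)
  } else {
    args$seed <- seed
    do.call(hierarchical_planted_graph, args)
  }
}

#' Run the full comparative modular-structure analysis
#'
#' Executes the whole study workflow on one network: load or generate the
#' input and take its giant component; cluster with greedy modularity (CNM)
#' and the map equation (infomap-style); evaluate modularity against a
#' degree-preserving rewired ensemble; compute cluster-size statistics, the
#' cumulative cluster-size curve, the natural modularity scale band and the
#' cross-partition overlap; build Z-P cartographies for both partitions;
#' score biological homogeneity (BHI) with the within-coarse-cluster label
#' shuffle null; test gene-set role enrichment (Fisher + BH and the
#' degree-matched bootstrap) for the gene set and its degree-truncated
#' variant under both partitions; and compare degree-bounded ROC/AUC of
#' participation (both resolutions), degree, betweenness and bridging
#' centrality, with a DeLong test between the two participation scores.
#'
#' Every stochastic stage derives its seed deterministically from the master
#' seed, so a rerun with the same config is fully reproducible.
#'
#' @param config Config list or path to a YAML config (see
#'   [read_run_config()]).
#' @param output_dir Optional output directory for TSV/JSON artifacts
#'   (overrides `config$output_dir`).
#' @return Object of class `mesocarto_report` (a list of all stage results),
#'   invisibly when writing artifacts.
#' @export
run_full_analysis <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  st <- utils::modifyList(default_settings(), config$settings %||% list())
  master <- config$seed %||% 1L
  outdir <- output_dir %||% config$output_dir
  fingerprint <- config_fingerprint(config[setdiff(names(config), "output_dir")])

  gen <- build_network(config, stage_seed(master, "generate"))
  net <- giant_component(gen$network)
  truth <- gen$truth

  fit_cnm <- cnm_cluster(net)
  fit_ifm <- infomap_cluster(net, seed = stage_seed(master, "infomap"),
                             n_trials = st$infomap_trials)
  part_cnm <- as_partition(fit_cnm)
  part_ifm <- as_partition(fit_ifm)
  q_cnm <- fit_cnm$modularity
  q_ifm <- modularity_q(net, part_ifm)

  rewired <- NULL
  if (st$rewire_ensemble > 0) {
    qs_cnm <- numeric(st$rewire_ensemble)
    qs_ifm <- numeric(st$rewire_ensemble)
    base_seed <- stage_seed(master, "rewire")
    for (r in seq_len(st$rewire_ensemble)) {
      rw <- degree_preserving_rewire(net, swaps_per_edge = st$swaps_per_edge,
                                     seed = (base_seed + r) %% 2147483647)
      rw <- giant_component(rw)
      qs_cnm[r] <- cnm_cluster(rw)$modularity
      fr <- infomap_cluster(rw, seed = (base_seed + r) %% 2147483647, n_trials = 1)
      qs_ifm[r] <- modularity_q(rw, as_partition(fr))
    }
    rewired <- list(q_cnm = qs_cnm, q_infomap = qs_ifm,
                    q_cnm_mean = mean(qs_cnm), q_cnm_sd = stats::sd(qs_cnm),
                    q_infomap_mean = mean(qs_ifm), q_infomap_sd = stats::sd(qs_ifm))
  }

  stats_cnm <- cluster_stats(net, part_cnm, reference = part_ifm)
  stats_ifm <- cluster_stats(net, part_ifm, reference = part_cnm)
  curve_cnm <- cumulative_cluster_size_curve(stats_cnm, igraph::vcount(net))
  curve_ifm <- cumulative_cluster_size_curve(stats_ifm, igraph::vcount(net))
  scale_band <- natural_scale(net)
  overlap <- partition_overlap(net, part_ifm, part_cnm)

  carto_cnm <- cartography_table(net, part_cnm, z_hub = st$z_hub, p_r1 = st$p_r1)
  carto_ifm <- cartography_table(net, part_ifm, z_hub = st$z_hub, p_r1 = st$p_r1)

  ann <- NULL
  bhi_res <- NULL
  if (!is.null(config$annotations)) {
    ab <- config$annotations
    ann <- if (!is.null(ab$gmt)) {
      as_annotation_map(read_gmt(ab$gmt))
    } else if (!is.null(ab$module_aligned)) {
      if (is.null(truth)) stopf("module_aligned annotations need a synthetic network")
      module_aligned_annotations(truth,
                                 n_classes_per_module = ab$module_aligned$n_classes_per_module %||% 1,
                                 noise = ab$module_aligned$noise %||% 0.2,
                                 seed = stage_seed(master, "annotations"))
    }
    if (!is.null(ann)) {
      bhi_res <- list(
        bhi_cnm = bhi(part_cnm, ann),
        bhi_infomap = bhi(part_ifm, ann),
        shuffle = bhi_shuffle_null(part_cnm, part_ifm, ann,
                                   n = st$bhi_shuffle_n,
                                   seed = stage_seed(master, "bhi"))
      )
    }
  }

  gs <- NULL
  enrich <- NULL
  roc <- NULL
  if (!is.null(config$gene_set)) {
    gb <- config$gene_set
    gs <- if (!is.null(gb$path)) {
      read_gene_set(gb$path)
    } else if (!is.null(gb$planted)) {
      planted_interface_geneset(net, part_ifm,
                                size = gb$planted$size %||% 60,
                                beta = gb$planted$beta %||% 5,
                                gamma = gb$planted$gamma %||% 1,
                                seed = stage_seed(master, "geneset"))
    }
    gs <- intersect(gs, igraph::V(net)$name)
    gs_trunc <- truncate_top_degree(gs, net, fraction = st$truncate_fraction)

    enrich_one <- function(carto, label) {
      full <- fisher_role_enrichment(carto, gs, p_adjust_n = st$p_adjust_n)
      boot <- degree_bootstrap_pvalue(net, carto, gs, n = st$bootstrap_n,
                                      seed = stage_seed(master, paste0("bootstrap_", label)))
      trunc_fisher <- fisher_role_enrichment(carto, gs_trunc, p_adjust_n = st$p_adjust_n)
      trunc_boot <- degree_bootstrap_pvalue(net, carto, gs_trunc, n = st$bootstrap_n,
                                            seed = stage_seed(master, paste0("bootstrap_", label, "_trunc")))
      tab <- data.frame(role = full$role,
                        n_nodes = full$n_nodes,
                        n_set = full$n_set,
                        p_adj = full$p_adj,
                        p_boot_adj = boot$p_boot_adj,
                        n_set_trunc = trunc_fisher$n_set,
                        p_adj_trunc = trunc_fisher$p_adj,
                        p_boot_adj_trunc = trunc_boot$p_boot_adj,
                        stringsAsFactors = FALSE)
      list(table = tab, fisher = full, bootstrap = boot,
           fisher_trunc = trunc_fisher, bootstrap_trunc = trunc_boot)
    }
    enrich <- list(cnm = enrich_one(carto_cnm, "cnm"),
                   infomap = enrich_one(carto_ifm, "infomap"))

    eval_nodes <- degree_bounded_nodes(net, percentile = st$roc_percentile)
    cent <- centrality_table(net)
    score_list <- list(
      participation_infomap = stats::setNames(carto_ifm$p, carto_ifm$node),
      participation_cnm = stats::setNames(carto_cnm$p, carto_cnm$node),
      degree = stats::setNames(as.numeric(cent$degree), cent$node),
      betweenness = stats::setNames(cent$betweenness, cent$node),
      bridging_centrality = stats::setNames(cent$bridging_centrality, cent$node)
    )
    rocs <- lapply(score_list, roc_auc, positives = gs, eval_nodes = eval_nodes)
    dl <- delong_test(score_list$participation_infomap, score_list$participation_cnm,
                      positives = gs, eval_nodes = eval_nodes)
    roc <- list(eval_nodes = eval_nodes, rocs = rocs, delong = dl,
                auc = vapply(rocs, function(r) r$auc, numeric(1)))
  }

  report <- structure(list(
    config = config, settings = st, fingerprint = fingerprint, seed = master,
    network = net, truth = truth,
    cnm = fit_cnm, infomap = fit_ifm,
    q_cnm = q_cnm, q_infomap = q_ifm, rewired = rewired,
    cluster_stats = list(cnm = stats_cnm, infomap = stats_ifm),
    curves = list(cnm = curve_cnm, infomap = curve_ifm),
    natural_scale = scale_band, overlap = overlap,
    cartography = list(cnm = carto_cnm, infomap = carto_ifm),
    bhi = bhi_res, gene_set = gs, enrichment = enrich, roc = roc
  ), class = "mesocarto_report")

  if (!is.null(outdir)) {
    write_report(report, outdir)
    return(invisible(report))
  }
  report
}

#' @export
print.mesocarto_report <- function(x, ...) {
  cat(sprintf("mesocarto run [%s]: N = %d, L = %d\n", x$fingerprint,
              igraph::vcount(x$network), igraph::ecount(x$network)))
  cat(sprintf("  CNM:     %d communities, Q = %.4f\n", x$cnm$n_communities, x$q_cnm))
  cat(sprintf("  infomap: %d modules,     Q = %.4f, codelength = %.3f bits\n",
              x$infomap$n_communities, x$q_infomap, x$infomap$codelength$bits))
  if (!is.null(x$overlap)) {
    cat(sprintf("  fine intra-pairs preserved in coarse: %.1f%% (reverse %.1f%%)\n",
                100 * x$overlap$a_pairs_in_b, 100 * x$overlap$b_pairs_in_a))
  }
  if (!is.null(x$bhi)) {
    cat(sprintf("  BHI: infomap %.3f vs CNM %.3f (shuffle p = %.4g)\n",
                x$bhi$bhi_infomap, x$bhi$bhi_cnm, x$bhi$shuffle$pooled$p_emp))
  }
  if (!is.null(x$roc)) {
    cat(sprintf("  AUC: P(infomap) %.3f vs P(CNM) %.3f, DeLong p = %.4g\n",
                x$roc$auc[["participation_infomap"]], x$roc$auc[["participation_cnm"]],
                x$roc$delong$p))
  }
  invisible(x)
}

# Write all pipeline artifacts as plain TSV/JSON under outdir.
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(outdir, name)
  write_partition(report$cnm$membership, fp("partition_cnm.tsv"))
  write_partition(report$infomap$membership, fp("partition_infomap.tsv"))
  write_merge_trace(report$cnm, fp("cnm_merge_trace.tsv"))
  write_tsv(report$cluster_stats$cnm, fp("cluster_stats_cnm.tsv"))
  write_tsv(report$cluster_stats$infomap, fp("cluster_stats_infomap.tsv"))
  write_tsv(report$curves$cnm, fp("cumulative_curve_cnm.tsv"))
  write_tsv(report$curves$infomap, fp("cumulative_curve_infomap.tsv"))
  write_cartography_table(report$cartography$cnm, fp("cartography_cnm.tsv"))
  write_cartography_table(report$cartography$infomap, fp("cartography_infomap.tsv"))
  if (!is.null(report$enrichment)) {
    write_tsv(report$enrichment$cnm$table, fp("enrichment_cnm.tsv"))
    write_tsv(report$enrichment$infomap$table, fp("enrichment_infomap.tsv"))
    for (nm in names(report$roc$rocs)) {
      write_tsv(report$roc$rocs[[nm]]$curve, fp(sprintf("roc_%s.tsv", nm)))
    }
  }
  summary <- list(
    fingerprint = report$fingerprint,
    seed = report$seed,
    n_nodes = igraph::vcount(report$network),
    n_edges = igraph::ecount(report$network),
    natural_scale = report$natural_scale,
    q_cnm = report$q_cnm,
    q_infomap = report$q_infomap,
    n_communities_cnm = report$cnm$n_communities,
    n_communities_infomap = report$infomap$n_communities,
    codelength_infomap = report$infomap$codelength$bits,
    rewired = if (!is.null(report$rewired)) {
      report$rewired[c("q_cnm_mean", "q_cnm_sd", "q_infomap_mean", "q_infomap_sd")]
    },
    overlap = unclass(report$overlap)[c("a_links_in_b", "b_links_in_a",
                                        "a_pairs_in_b", "b_pairs_in_a")],
    role_counts = list(cnm = as.list(role_counts(report$cartography$cnm)),
                       infomap = as.list(role_counts(report$cartography$infomap))),
    bhi = if (!is.null(report$bhi)) {
      list(cnm = report$bhi$bhi_cnm, infomap = report$bhi$bhi_infomap,
           shuffle_p = report$bhi$shuffle$pooled$p_emp,
           shuffle_null_mean = report$bhi$shuffle$pooled$null_mean)
    },
    auc = if (!is.null(report$roc)) as.list(report$roc$auc),
    delong = if (!is.null(report$roc)) {
      report$roc$delong[c("auc_a", "auc_b", "z", "p")]
    }
  )
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  log_lines <- c(
    sprintf("mesocarto %s", as.character(utils::packageVersion("mesocarto"))),
    sprintf("R %s | igraph %s", getRversion(), as.character(utils::packageVersion("igraph"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("config fingerprint %s, master seed %s", report$fingerprint, report$seed)
  )
  writeLines(log_lines, fp("run.log"))
  invisible(outdir)
}
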