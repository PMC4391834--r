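# mesocarto

Comparative modular-structure analysis of protein interaction networks (and
other undirected networks): how the *choice of community-detection
algorithm* conditions every downstream meso-scale analysis.

## The problem

Protein interaction networks (PINs) are modular, but "the" modular
decomposition is ill-posed: different well-performing algorithms return
partitions at different granularities. `mesocarto` pairs the two paradigmatic
approaches —

* **greedy modularity maximization** (Clauset–Newman–Moore), which optimizes
  $Q = \frac{1}{2L}\sum_{ij}(A_{ij} - \frac{k_i k_j}{2L})\,\delta(C_i,C_j)$
  and is subject to the *resolution limit*: communities with fewer than
  $\sim\sqrt{L}$ internal links tend to be merged;
* **two-level map-equation minimization** (infomap-style), which minimizes
  the expected description length
  $L(M) = q\,H(Q) + \sum_m (p_m + q_m)\,H(P^m)$
  of a random walk and resolves much finer structure —

and quantifies the downstream consequences:

* **Cluster-size structure** — internal-link counts, the cumulative
  cluster-size curve and the natural modularity scale band
  $[\sqrt{L/2}, \sqrt{2L}]$; nesting/overlap statistics between the two
  partitions (preserved internal links and intra-cluster node pairs,
  fraction of broken links).
* **Z–P cartography** — within-module degree
  $Z_i = (k_i - \bar{k}_{C_i})/\sigma_{k_{C_i}}$, participation coefficient
  $P_i = 1 - \sum_C (k_{iC}/k_i)^2$, and the seven Guimerà–Amaral universal
  roles (ultra-peripheral R1 … kinless hub R7).
* **Biological congruence** — the Biological Homogeneity Index (BHI) of a
  partition against functional annotations, with a within-coarse-cluster
  label-shuffle null.
* **Gene-set role enrichment** — one-sided Fisher tests with BH correction,
  a *degree-matched bootstrap* control (random gene sets with the same
  degree distribution), top-degree gene-set truncation, and degree-bounded
  ROC/AUC comparison of topological predictors with DeLong's paired test.
* **Null models & generators** — Erdős–Rényi G(n,m) and degree-preserving
  rewired controls; seeded two-scale planted networks (nested stochastic
  block model plus explicit high-participation interface nodes),
  module-aligned annotations and interface-biased gene sets, so the entire
  workflow is testable end to end without any external download.

Inputs are plain edge lists (TSV/SIF), GMT annotations and one-id-per-line
gene sets, so real datasets (e.g. a HIPPIE-style PIN with a GenAge-style
gene list) drop in without code changes.

## Worked example

```r
library(mesocarto)

cfg <- list(
  seed = 7,
  network     = list(synthetic = list(generator = "hierarchical")),
  annotations = list(module_aligned = list(noise = 0.2)),
  gene_set    = list(planted = list(size = 60, beta = 5, gamma = 1)),
  settings    = list(infomap_trials = 10, rewire_ensemble = 20,
                     bhi_shuffle_n = 200, bootstrap_n = 200)
)
rep <- run_full_analysis(cfg)
print(rep)
#> mesocarto run [0c923703]: N = 204, L = 964
#>   CNM:     6 communities, Q = 0.6404
#>   infomap: 18 modules,     Q = 0.6397, codelength = 5.805 bits
#>   fine intra-pairs preserved in coarse: 96.9% (reverse 30.4%)
#>   BHI: infomap 0.649 vs CNM 0.258 (shuffle p = 0.004975)
#>   AUC: P(infomap) 0.778 vs P(CNM) 0.690, DeLong p = 0.04836
```

Reading this: both partitions reach nearly the same modularity (Q ≈ 0.64),
yet the map equation resolves 18 modules where greedy modularity returns 6 —
the fine partition nests almost perfectly inside the coarse one (96.9% of
its intra-cluster pairs preserved) but not vice versa. The fine modules are
far more functionally homogeneous (BHI 0.649 vs 0.258; higher than all 200
within-cluster label shuffles), and fine-resolution participation is the
better predictor of the planted interface gene set on mid/low-degree nodes
(AUC 0.778 vs 0.690).

The role-enrichment table mirrors this: only the *kinless* category (R4)
is enriched in the gene set, and the signal survives the degree-matched
bootstrap:

```r
rep$enrichment$infomap$table[, c("role", "n_nodes", "n_set", "p_adj", "p_boot_adj")]
#>   role n_nodes n_set        p_adj p_boot_adj
#> 1   R1      13     0 1.000000e+00 1.00000000
#> 2   R2     162    40 1.000000e+00 1.00000000
#> 3   R3      16     8 2.070013e-01 0.57462687
#> 4   R4      11    11 4.947519e-06 0.03482587
#> 5   R5       0     0 1.000000e+00 1.00000000
#> 6   R6       2     1 1.000000e+00 1.00000000
#> 7   R7       0     0 1.000000e+00 1.00000000
```

The resolution limit in isolation:

```r
rc <- ring_of_cliques(30, 5)
cnm_cluster(rc$network)
#> Greedy modularity (CNM) clustering: 15 communities, Q = 0.8879
infomap_cluster(rc$network, seed = 1)
#> Map-equation (infomap-style) clustering: 30 modules, codelength = 3.2106 bits
```

Thirty 5-cliques joined in a ring exceed the $\sqrt{2L}$ scale, so greedy
modularity merges neighboring cliques pairwise while the map equation keeps
all thirty.

Individual stages are available as plain functions
(`read_edge_list`, `giant_component`, `cnm_cluster`, `infomap_cluster`,
`modularity_q`, `map_equation`, `cartography_table`, `bhi`,
`bhi_shuffle_null`, `fisher_role_enrichment`, `degree_bootstrap_pvalue`,
`roc_auc`, `delong_test`, …); `inst/scripts/run-analysis.R` is a thin
command-line wrapper around `run_full_analysis()`.

## Methods

See the methods vignette (`vignettes/mesocarto-methods.Rmd`) for model
details, parameter choices, numerical conventions and known limitations.
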