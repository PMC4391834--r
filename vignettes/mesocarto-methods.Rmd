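---
title: "Methods: comparative modular structure and Z-P cartography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative modular structure and Z-P cartography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mesocarto)
```

## Scope and rationale

`mesocarto` studies a single methodological question with concrete
biological consequences: *how does the granularity of a network's modular
decomposition condition downstream meso-scale analyses?* The package
implements two classical community-detection objectives, a cartographic
description of nodes relative to a partition, a biological-congruence score,
and a degree-controlled gene-set enrichment workflow, all behind stable
function interfaces, plus seeded generators that reproduce the structural
features those analyses rely on. Every quantitative claim the package makes
about itself is computed by its test suite or by `scripts/acceptance.R` —
nothing below reports numbers that are not re-derived at run time.

## Community detection

### Modularity and the greedy merge

For an undirected simple graph with adjacency \(A_{ij}\), degrees \(k_i\)
and \(L\) edges, modularity of a partition \(C\) is

\[ Q = \frac{1}{2L}\sum_{ij}\Big(A_{ij}-\frac{k_ik_j}{2L}\Big)\,\delta(C_i,C_j)
   \;=\; \sum_c\Big[\frac{l_c}{L}-\Big(\frac{d_c}{2L}\Big)^2\Big], \]

with \(l_c\) internal edges and \(d_c\) the degree sum of community \(c\).
`modularity_q()` evaluates the community-sum form exactly; the test suite
checks it against a literal double-sum oracle to 1e-12.

`cnm_cluster()` is the agglomerative greedy optimizer: start from
singletons, repeatedly merge the connected community pair with the largest
\(\Delta Q = l_{ab}/L - 2a_a a_b\) (merging disconnected pairs can never
increase Q, so they are never candidates), and return the cut of the merge
path with maximal Q. Determinism is part of the contract: ties in
\(\Delta Q\) are resolved toward the lexicographically smallest label pair,
a merged community inherits the smaller label, and the returned Q is
re-verified against the direct formula. Greedy merging is not globally
optimal; on small graphs the suite bounds it at \(\ge 90\%\) of the
exhaustive-search optimum.

### The two-level map equation

`map_equation()` scores a partition by the expected per-step description
length of an unrecorded random walk under a two-level codebook. On a
connected undirected graph the stationary visit rates are closed-form,
\(p_i = k_i/2L\), and the exit rate of module \(m\) is
\(q_m = b_m/2L\) with \(b_m\) its boundary edge count:

\[ L(M) = q\,H(Q) + \sum_m (p_m+q_m)\,H(P^m), \qquad q=\sum_m q_m, \]

logarithms base 2 and \(0\log 0 = 0\). For the one-module partition this
reduces exactly to the entropy of \(\{k_i/2L\}\), which the tests assert.
Disconnected input is rejected rather than patched with teleportation: the
package always clusters the giant component, where the walk is ergodic.

`infomap_cluster()` minimizes the codelength with the standard two-phase
search: seeded sweeps of single-node moves to neighboring modules (kept when
they reduce the codelength, evaluated incrementally from module-level
aggregates), followed by aggregation of modules into super-nodes and
repetition on the coarse graph, iterated until no improvement; the best of
`n_trials` restarts (default 10) is returned. Two properties are enforced by
test: on small connected graphs the search attains the exhaustive-minimum
codelength in \(\ge 90\%\) of instances, and on a planted two-scale graph it
agrees with the independent reference implementation in `igraph` to within
rounding.

### Resolution

The two objectives disagree in a characteristic way. Modularity
maximization cannot resolve communities whose internal link count falls
below the natural scale \(\lambda=\sqrt{L}\) (the package reports the
symmetric band \([\sqrt{L/2},\sqrt{2L}]\); the alternative reading
\(\sqrt{L}/2\) of the lower edge is a factor \(\sqrt 2\) away and does not
change any conclusion). On a ring of 30 5-cliques greedy modularity merges
neighboring cliques while the map equation keeps all thirty — the package's
canonical demonstration (`ring_of_cliques()`).

## Cartography

Given a partition, each node gets a within-module degree z-score
\(Z_i=(k_i-\bar k_{C_i})/\sigma_{k_{C_i}}\) and a participation coefficient
\(P_i = 1-\sum_C (k_{iC}/k_i)^2\). Conventions (configurable, recorded in
the table's metadata):

* \(\sigma\) is the population (divide-by-n) standard deviation; a
  degenerate community (\(\sigma=0\)) gives \(Z=0\);
* isolated nodes get \(P=0\);
* roles: hubs are \(Z \ge 2.5\) (inclusive); non-hub boundaries at
  \(P = 0.05\) (operationalizing "P approximately 0" for the
  ultra-peripheral class), \(0.625\), \(0.8\); hub boundaries at \(0.3\),
  \(0.75\). All intervals are left-closed/right-open except the top
  category. A 14-point boundary suite pins every threshold.

Because a coarser partition has fewer, larger modules, merging communities
can only concentrate a node's link shares and thus lower \(P\) — the
package tests this monotonicity directly, and it is the mechanism behind
the empirical finding that coarse-resolution cartographies deplete the
high-participation ("kinless") roles.

## Biological homogeneity

`bhi()` implements the annotation-homogeneity index

\[ BHI = \frac{1}{K}\sum_k \frac{1}{n_k(n_k-1)}
   \sum_{i\neq j\in C_k} 1\{\mathrm{cls}(i)\cap \mathrm{cls}(j)\neq\emptyset\}, \]

over communities with at least two annotated members; unannotated nodes are
excluded from pair counting. All annotation classes are pooled jointly (no
ontology-branch separation — term ancestry and evidence codes are out of
scope). `bhi_shuffle_null()` permutes the fine-partition labels *within each
coarse community* so that community sizes, the fine-label multiset and the
annotation of every node are all preserved; the empirical p-value uses the
\((1+r)/(n+1)\) estimator. The null's mean reproduces the BHI of the
structure-less coarse cluster, which the tests verify within 3 standard
errors. When the two partitions are not strictly nested (the usual case for
two independent algorithms), nodes whose fine module spans several coarse
communities are excluded with a warning.

## Degree-controlled enrichment

Role enrichment of a gene set uses the one-sided Fisher exact test per role
(computed as the hypergeometric tail; the suite checks it against explicit
`choose()`-sum enumeration over all tables with margins up to 30) with
Benjamini–Hochberg correction across the 7 roles of one partition (family
size configurable to 14 for joint correction across two partitions).

Because phenotype gene sets are degree-biased, Fisher significance can be a
pure degree artifact. `degree_bootstrap_pvalue()` therefore draws `n`
(default 1000) control sets matching the query's degree multiset — each
gene replaced by a uniform draw from the pool of equal-degree nodes, without
replacement within a realization; an exhausted pool widens geometrically by
factor \(\sqrt2\) around the target degree (logged). The bootstrap p-value
\((1+r)/(n+1)\) is never exactly zero. Being a count statistic, it is
*super-uniform* under the null; the acceptance suite checks calibration with
the standard randomized tie-breaking construction, which is exactly uniform
for exchangeable draws.

Complementary pieces: `truncate_top_degree()` removes the
\(\lceil 0.1\,|S|\rceil\) highest-degree members (ties resolved
deterministically, lower ids removed first); `degree_bounded_nodes()` keeps
nodes up to the lower nearest-rank 90th degree percentile;
`roc_auc()`/`delong_test()` compare topological predictors on that subset.
AUC is the tie-aware Mann–Whitney estimate (asserted as an identity against
`wilcox.test`); the DeLong test uses the placement-based covariance of the
paired AUC difference with a normal approximation, returning \(z=0, p=1\)
for identical scores (the reason it is implemented here rather than taken
from `pROC`, which is used as the independent cross-check in tests).

## Synthetic data: what it emulates, and what it does not

`hierarchical_planted_graph()` draws a nested stochastic block model:
`n_macro = 4` coarse groups × `micro_per_macro = 4` fine modules ×
`micro_size = 12` nodes, with edge probabilities `p_in_micro = 0.6`,
`p_in_macro = 0.04`, `p_between = 0.003`. These defaults were calibrated
once, before being wired into any test, so that the planted fine partition
is the *codelength optimum* (confirmed independently with `igraph`'s
infomap at calibration time) while greedy modularity
still merges fine modules into \(\le 8\) communities — i.e., the two
algorithms genuinely disagree in the direction the analysis studies. At
appreciably denser inter-module probabilities the map-equation optimum
itself coarsens and *no* correct minimizer recovers the fine truth; that
regime is a property of the objective, not of an implementation.

A homogeneous block model of this size cannot populate the kinless region
of the Z–P plane: a typical node has \(\sim 70\%\) of its links internal,
capping \(P\) near 0.5. Real interaction networks do harbor a minority of
high-participation interface proteins, so the generator plants
`n_interface = 12` explicit interface nodes (\(\approx 6\%\) of the
network): each gets a home module, 3±1 home links and 8±2 single links into
distinct foreign modules. Their participation lands near 0.85 while their
total degree stays below the hub threshold, and the link-count jitter
spreads them across common degree values so they do not form their own
degree class (which would make any degree-matched control set reproduce
them trivially).

`planted_interface_geneset()` samples without replacement with weight
\(\exp(\beta P_i)\,k_i^{\gamma}\): \(\beta\) creates the interface bias
(\(\beta=5\) makes an interface node roughly an order of magnitude more
likely than a typical node, consistent with the few-fold interface
enrichment reported for aging genes), \(\gamma=1\) adds the heavy-tailed
degree bias such phenotype sets display.
`module_aligned_annotations()` gives each fine module dedicated classes;
with probability `noise` a node inherits the classes of a *uniformly*
drawn module, so `noise = 1` is exactly module-independent (which makes the
shuffle-null calibration test well-posed) and `noise = 0.2` leaves strong
but imperfect alignment — BHI of the fine truth ≈ 0.7 against ≈ 0.3 for the
coarse truth.

What passing on these graphs does **not** show: robustness to the heavy
power-law degree tails, annotation incompleteness and annotation bias of a
real PIN; scalability beyond \(10^4\)-node networks (the greedy and search
loops are plain R, chosen for transparency over speed); or behavior on
weighted/directed interactomes, which are out of scope throughout.

## Pipeline, determinism and problem sizes

`run_full_analysis()` executes the whole study from a config list or YAML
file and optionally writes all artifacts (partitions, merge trace, cluster
stats, curves, cartographies, enrichment tables, ROC curves, a JSON
summary stamped with a config fingerprint, and a run log). Every stochastic
stage derives its own seed deterministically from the master seed and a
stage name, so reruns are byte-identical at the JSON level — a property the
test suite asserts literally.

Ensemble sizes default to the study scale (1000 rewired networks, 1000
bootstrap realizations, 1000 label shuffles) and scale down through the
config. The shipped tests and the acceptance script run the synthetic study
at 204 nodes / ~1000 edges with 10–50 rewirings, 200–1000 bootstrap
realizations and 200–1000 shuffles; exhaustive oracles (all set partitions,
all 2×2 tables) are applied up to 8 nodes and margin 30 respectively. These
sizes were chosen so the full validation remains a desk-scale computation
while every statistical check retains enough resolution to fail loudly if
an implementation regresses.

## Known limitations

* Two-level (flat) map equation only; no hierarchical codebooks,
  teleportation, weights or directions.
* Greedy CNM explores a single merge path; degenerate near-optimal
  partitions of very different granularity (a known property of the
  modularity landscape) are reported only through the returned best cut and
  the merge trace.
* BHI treats annotation classes as flat sets; ontology structure is
  ignored.
* The degree-matched sampler widens pools geometrically on exhaustion,
  which slightly relaxes the matching for extreme-degree genes (logged when
  it happens).
* P-value floors are \(1/(n+1)\) by construction; reported zeros never
  occur, and strong signals saturate at the floor for small `n`.
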