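# nmigraph

Graph-theoretical analysis of task-fMRI functional brain networks, built
around normalized-mutual-information (NMI) connectivity. The package is
aimed at researchers who compare the functional network organisation of
subject groups — e.g. patients with a focal movement disorder such as
writer's cramp against healthy controls — from blocked-task fMRI: it turns
per-subject ROI time series into weighted whole-brain graphs, averages them
into group networks, and characterises and compares those networks with the
standard toolbox of weighted network statistics, consensus community
detection, hub classification and permutation inference. Because studies of
this kind often cannot share raw imaging data, the package also ships a
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes (block design, planted modules, group effects, motion
artifacts), so the entire pipeline is testable and demonstrable without any
download.

## The method

For each subject, volumes with differential head movement > 0.5 mm per TR
are censored and only task-block volumes are retained. Pairwise dependence
between ROI time series is estimated as

> NMI(x, y) = I(x; y) / sqrt(H(x) · H(y)) ∈ [0, 1],

the histogram mutual information normalized by the geometric mean of the
Shannon entropies — a non-negative analogue of the correlation matrix with
0 meaning independence and 1 full dependence. The resulting ROI × ROI
matrix defines a weighted undirected graph, which is thresholded to 50%
edge density (weakest edges removed), after which nodes holding fewer than
5% of possible connections are eliminated. Per group, subject graphs are
reduced to the common node set, averaged edge-wise, and re-thresholded to
50%; the number of surviving nodes is itself a reported statistic of
network recruitment.

On each group network the package computes normalized nodal degree and
strength (k/N, s/N), the weighted clustering coefficient (geometric mean of
triangle weights, Onnela form), and global efficiency (mean inverse
shortest-path length with lengths 1/w). Community structure is found by
maximizing Newman's modularity Q with a Kernighan–Lin refinement heuristic,
run 100 times and combined into a consensus partition (label-aligned
per-node mode, node 1 as reference). Decompositions are compared by the
partition distance pd = VI(P,Q)/log N (normalized variation of
information). Nodes are classed as connector hubs, provincial hubs
(degree & strength ≥ 1 SD above the mean, split at 90% of the maximum
participation coefficient 1 − 1/M), high-influence nodes (non-hubs in the
top 30% for both degree and strength), or other. Group differences in the
metrics are tested with two-tailed Monte-Carlo permutation t-tests (20,000
randomizations, exact enumeration for small designs) under Bonferroni
correction.

## A worked example

A small synthetic two-group study: 30 ROIs in three planted modules, eight
subjects per group, with stronger within-module coupling in group B.

```r
library(nmigraph)

spec <- cohort_spec(
  n_per_group = c(A = 8, B = 8), n_rois = 30,
  design = make_block_design(8, 30, 30, 2.5),
  structure = planted_structure(
    rep_len(1:3, 30), within_coupling = 0.4, between_coupling = 0.05,
    group_effects = list(B = list(within_coupling = 0.95))),
  seed = 1)

report <- run_group_analysis(
  analysis_config(spec, n_mod_runs = 20, n_perm = 2000,
                  m_comparisons = 4, seed = 101))
print(report)
```

```
Group network analysis report
  A (n=8): 30 of 30 regions in network (density 0.50)
    degree 0.48 ± 0.12 | strength 0.07 ± 0.02 | clustering 0.07 ± 0.01 | efficiency 0.11 ± 0.01
    3 modules (Q=0.123) | hubs: 3 connector, 0 provincial; 6 high-influence
  B (n=8): 30 of 30 regions in network (density 0.50)
    degree 0.48 ± 0.09 | strength 0.08 ± 0.01 | clustering 0.11 ± 0.02 | efficiency 0.13 ± 0.01
    3 modules (Q=0.389) | hubs: 3 connector, 0 provincial; 6 high-influence
  A_vs_B: pd = 0.516 (p = 0.02449 over 30 shared nodes)
    degree_norm   t =   0.000, p = 1
    strength_norm t =  -3.466, p = 0.0004998 *
    clustering    t =  -8.162, p = 0.0004998 *
    efficiency    t =  -6.631, p = 0.0004998 *
    (Bonferroni threshold p < 0.0125)
```

Reading the output: both groups keep all 30 regions at exactly 50% edge
density (with real, noisier data the elimination step typically drops
regions, and the "k of N regions" counts differ between groups). The
consensus decomposition finds the three planted modules in each network,
with the much stronger coupling in group B visible as a higher modularity
Q. Mean normalized degree is identical by construction — both networks sit
at the same density — while the coupling contrast raises group B's edge
weights and therefore its strength, clustering and efficiency; the
node-wise permutation tests flag all three at the Bonferroni-corrected
threshold (`*`). The partition distance pd = 0.516 with p ≈ 0.02 says the
two decompositions agree more than chance relabelings would.
`summary(report)` returns the same numbers as a data frame;
`write_report_json()` serializes them.

A study-scale preset (212 ROIs, 360 volumes, 26 + 20 subjects) is available
as `wc_study_preset()`; it runs the identical pipeline in a few minutes.

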