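---
title: "Graph-theoretical analysis of task-fMRI functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical analysis of task-fMRI functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nmigraph implements a complete group-comparison pipeline for weighted
functional brain networks built from blocked task-fMRI: normalized mutual
information (NMI) connectivity, density-thresholded weighted graphs with
nodal elimination, group-averaged networks, weighted network metrics,
consensus modular decomposition, a hub taxonomy, and Monte-Carlo permutation
inference. This vignette explains the model behind each stage, the tunable
parameters and their defaults, the synthetic-cohort generator that stands in
for imaging data, and the numerical choices made where the procedure leaves
room.

## The connectivity model

Each subject contributes a matrix of ROI-averaged BOLD signal over volumes.
Two preprocessing masks restrict which volumes enter connectivity
estimation:

* **Motion censoring** (`censor_motion()`): volumes with differential
  movement strictly greater than 0.5 mm per TR are removed. A volume at
  exactly 0.5 mm is kept — the rule is "greater than", read literally — and
  censored volumes are dropped outright, never interpolated.
* **Task selection** (`select_task_volumes()`): only volumes acquired during
  task blocks are used. The two masks are intersected, so the order of
  censoring and task selection cannot matter.

Pairwise dependence between the retained series of ROIs $i$ and $j$ is the
normalized mutual information

$$\mathrm{NMI}(x, y) \;=\; \frac{I(x; y)}{\sqrt{H(x)\,H(y)}},$$

with $I$ and $H$ the plug-in mutual information and Shannon entropies of
equal-width histograms. NMI keeps the non-zero structure of a correlation
matrix while being non-negative, lies in $[0, 1]$ (0 = independence, 1 =
full dependence), and is invariant to the logarithm base because the base
cancels in the ratio. Internally all entropies use natural logs.

Numerical choices for the estimator:

* **Bin count.** The procedure that motivated this package does not state a
  discretization, so the package defaults to the standard square-root
  heuristic, $\lceil\sqrt{n}\rceil$ equal-width bins per series over its own
  observed range (14 bins for 180 retained volumes), configurable via
  `n_bins` everywhere. The joint histogram reuses the same per-axis edges.
  Plug-in MI at this bin count carries a well-known positive bias of roughly
  $(k-1)^2/2n$ nats; because every ROI pair of a subject shares $n$ and $k$,
  the bias is common to all entries and the downstream density thresholding
  — which only uses ranks — is insensitive to it.
* **Degenerate series.** A constant ROI has zero entropy; its NMI is defined
  as 0 and flagged (`degenerate_rois`), never NaN, so matrices stay valid.
* **Diagonal.** Fixed at 0: graphs are simple.

`build_connectivity_matrix()` computes all pairwise joint entropies in one
indicator-matrix product followed by a block aggregation, which is
algebraically identical to calling `nmi_coefficient()` per pair (the test
suite asserts exact agreement between the two routes) and makes a
212-ROI × 180-volume subject take seconds rather than minutes.

## Graph construction

Subject matrices become weighted undirected graphs (`brain_graph`) and pass
through four stages, each with the conventional default:

1. **Density thresholding** (`threshold_to_density()`, target 0.5): the
   weakest edges are removed until edge density reaches the target, because
   denser networks drift toward random-graph behaviour. Exactly
   $\lfloor 0.5\,N(N-1)/2\rfloor$ strongest edges are retained. Weight ties
   break by ascending lexicographic node-index pair, so results are
   bit-reproducible even with coarse binning.
2. **Nodal elimination** (`eliminate_sparse_nodes()`, 5%): nodes with
   strictly fewer than 5% of possible connections — counted against the node
   total at entry to this step — are removed once (no fixed-point
   iteration), followed by a single sweep dropping nodes left with no edges.
3. **Group reduction** (`reduce_to_common_nodes()`): each group keeps only
   nodes present in every subject of that group.
4. **Group averaging** (`group_average_network()`): edge weights are
   arithmetic means of the subjects' thresholded matrices (absent edges
   enter as zeros), and the averaged network is re-thresholded to 50%.

The elimination makes node counts a reported statistic: different groups can
legitimately recruit different network spaces, and the per-group "$k$ of
$N$ regions" line in the report reflects that. Because degree and strength
are normalized by the node count and all networks sit at the same density,
the metrics remain comparable across spaces.

## Network metrics

On a group network with $N$ nodes and weights $w_{ij}\in[0,1]$:

* **Normalized degree** $k_i/N$ and **normalized strength** $s_i/N$ with
  $k_i$ the edge count and $s_i$ the weight sum at node $i$.
* **Weighted clustering** (segregation): the Onnela-style geometric-mean
  form $C_i = \frac{2}{k_i(k_i-1)}\, t_i$, $t_i = \tfrac12 \sum_{j,h}
  (w_{ij} w_{ih} w_{jh})^{1/3}$, which is exactly "the geometric mean of
  weights in triangles around the node"; $C_i = 0$ for $k_i < 2$. Weights
  are already in $[0,1]$, so no re-normalization by the maximum weight is
  applied, and $C_i$ is homogeneous of degree one in a global weight
  rescaling.
* **Global efficiency** (integration): mean inverse shortest-path length
  over ordered pairs with edge length $1/w_{ij}$; disconnected pairs
  contribute 0 (the standard convention). Shortest paths use Dijkstra (via
  igraph); the test suite checks the result against an independent
  Floyd–Warshall implementation.

## Modular decomposition

Partitions are scored by Newman's weighted modularity
$Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} - \frac{s_i s_j}{2m}\right]
\delta(c_i, c_j)$. A single optimization run (`optimize_modularity()`)
starts from singleton modules and alternates two phases until a full cycle
stops improving $Q$: greedy agglomeration of module pairs with positive
gain, and Kernighan–Lin refinement passes in which every node is tentatively
reassigned once — accepting the locally best move even when its gain is
negative, then rolling back to the best prefix of the move sequence. The
negative-gain tunneling is what the Kernighan–Lin heuristic contributes over
plain greedy sweeps; on all graphs small enough for exhaustive search the
run recovers the global optimum (a tested property). Each run performs
internal restarts and returns the best partition: the first restart follows
the canonical schedule (singletons, best-gain merges), later ones
diversify by starting from a random coarse partition and sampling uniformly
among positive-gain merges. The default restart count scales inversely with
graph size (`max(4, ceiling(192/N))`) — on tiny graphs a restart costs
microseconds while local optima weigh heaviest, so the budget is spent
there. All randomness — sweep order, tie-breaks, merge draws, restart
initializations — derives from the run seed.

Because module labels are nominal and the heuristic is randomized,
`consensus_partition()` runs the optimizer `n_runs = 100` times, aligns
every run to the first by greedy maximum-overlap matching of the module
contingency table, takes the per-node modal aligned label, applies one final
refinement pass so the consensus is itself a local optimum, and relabels
modules in order of first appearance so the module containing node 1 is
always module 1. "Averaging nodal module assignments" is only meaningful
after such an alignment; the label-aligned per-node mode is the
implementation chosen here, recorded in the report provenance.

Partitions are compared by the normalized variation of information,
$\mathrm{pd} = \big[H(P) + H(Q) - 2 I(P;Q)\big] / \log N \in [0,1]$, zero
exactly for identical partitions up to relabeling. When two group networks
span different node sets, pd is computed on their shared nodes.

## Hub taxonomy

Using the group network and its consensus partition:

* **Hub**: degree and strength both at least one sample standard deviation
  (n − 1 denominator) above the network mean. If a metric's SD is zero
  (fully regular network) the comparison degenerates to strictly above the
  mean, so such networks have no hubs.
* **Connector vs provincial hub**: the degree-based participation
  coefficient $pc_i = 1 - \sum_m (k_{im}/k_i)^2$ is bounded by $1 - 1/M$
  for $M$ modules; hubs reaching 90% of that theoretical maximum are
  connectors, the rest provincial. With $M = 1$ the bound degenerates to 0
  and every hub is provincial (flagged).
* **High-influence node**: a non-hub in the top 30% for both degree and
  strength. Ranking uses minimum-rank ties over all nodes (hubs are excluded
  after ranking); if ties push the candidate set past
  $\lceil 0.3N\rceil$ it is truncated in node order, so fully tied networks
  still yield a deterministic selection.

Hub analysis is descriptive — classes are reported and compared across
groups (`compare_hub_tables()`), not tested statistically.

## Permutation inference

Group differences in the four metrics are assessed with a two-tailed
Monte-Carlo permutation t-test (`permutation_ttest()`, default 20,000
randomizations): Welch's t on the observed labels, a null built by
reassigning pooled observations to groups of the original sizes, and
add-one-smoothed p-values $(\#\{|t^*|\ge|t_{\mathrm{obs}}|\}+1)/(n_{\mathrm
perm}+1)$. When the label-assignment space has at most 10,000 elements the
test enumerates it exhaustively and is exact. The default Bonferroni divisor
is `m_comparisons = 20`, giving the conventional $p < 0.0025$ threshold at
$\alpha = 0.05$.

Two design choices deserve emphasis, as the motivating procedure leaves both
open:

* **Permutation unit.** The pipeline compares two *group networks*, each a
  single graph, and reports node-wise mean ± SD per metric; the only
  reading consistent with those dispersions is that the per-node metric
  values are the observations, and permutation reassigns node-to-network
  labels. This is recorded in the report provenance. Node-wise values
  within a network are not strictly independent, so with very small cohorts
  the group networks themselves are noisy and the test can be
  anticonservative; the packaged power experiment therefore uses eight or
  more subjects per group, where the calibration checks hold. Global
  efficiency, a scalar, is tested through its per-node decomposition
  $e_i = \frac{1}{N-1}\sum_j 1/d_{ij}$ (whose mean is the global
  efficiency).
* **Partition-distance test.** The null permutes one partition's labels
  across nodes, preserving module sizes, and by default asks whether the
  observed pd is *smaller* than chance (`alternative = "less"`): a
  significant result means the two decompositions agree beyond chance. The
  direction is configurable.

## The synthetic-cohort generator

No imaging data ships with the package; `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes, and every test
runs on such cohorts. Each module $m$ has an i.i.d. standard-Gaussian latent
series active only during task volumes; ROI $i$ in module $m$ observes

$$x_i(t) = \mathrm{task}(t)\,\big[\,w\, z_{m}(t) + b\, g(t)\,\big]
  + \sigma\,\varepsilon_i(t),$$

with $w$ the within-module coupling amplitude, $b$ a between-module leakage
through one shared latent $g$, and $\sigma$ the observation-noise SD
(default 1). Restricting the latent signal to task volumes mirrors the
analysis using task volumes only: rest volumes carry no community structure,
so selecting task volumes is not merely valid but necessary for recovery.
Group effects are expressed as coupling overrides and per-group
"inactive" ROI sets (pure-noise regions emulating areas a group fails to
recruit). Motion traces are a uniform 0–0.2 mm baseline with spikes of
1.0 mm at Bernoulli(0.02) volumes, exercising the censoring path
deterministically; per-subject seeds derive from the master seed, so a
cohort spec reproduces bit-identically.

The default study-scale preset (`wc_study_preset()`) emulates the motivating
design: 212 ROIs (the 142/36/34 cortical/subcortical/cerebellar split is
available through `make_atlas_fixture()` for the volumetric-extraction
path), 360 volumes as 15 blocks of 30 s task + 30 s rest at TR = 2.5 s, 26
control and 20 patient subjects, three planted modules, a stronger
within-module coupling in the patient group (driving the higher-clustering
contrast) and a 40-ROI inactive set.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: hemodynamic response convolution and autocorrelated
scanner noise (volumes are i.i.d. given the latents), realistic anatomy or
distance-dependent connectivity, heterogeneous per-subject coupling, and
global signal confounds. In particular, pure-noise ROIs in a synthetic
cohort still share the estimator's common MI bias with every other node, so
the 5% nodal-elimination step rarely fires at the 212-node scale here,
whereas on real data weakly connected regions do fall out; the elimination
path is exercised directly by unit tests on constructed graphs.

## Problem sizes and runtime choices

The packaged experiments are sized for a laptop-class single core: oracle
equivalences run on 5–9-node graphs against exhaustive or $O(N^3)$
references; planted-partition recovery uses 60-ROI, 3-module single-subject
cohorts (within 0.9, between 0, ten seeds) with full 100-run consensus;
permutation calibration uses 500 null replicates of 20 + 20 observations at
1,000 randomizations; the power experiment uses 8 + 8 subjects over 30 ROIs;
and one full study-scale run (212 ROIs, 46 subjects, all defaults including
20,000 randomizations) validates the end-to-end pipeline. Heavier versions
of the same experiments only tighten Monte-Carlo error, not the logic.

## Known limitations

* The histogram NMI estimator is biased upward at small sample counts; the
  pipeline's rank-based thresholding is immune, but raw NMI values should
  not be compared across designs with different retained-volume counts or
  bin settings.
* Node-wise permutation tests on two group networks inherit the
  independence caveat above.
* The consensus rule (label-aligned per-node mode) is one of several
  defensible readings of "average nodal module assignment"; it is flagged in
  the provenance so reports are explicit about it.
* `eliminate_sparse_nodes()` is deliberately single-pass; a cascade of
  disconnections beyond the final isolate sweep is not iterated.

## A worked example

```{r, eval = FALSE}
library(nmigraph)

spec <- wc_study_preset(seed = 1)
cfg  <- analysis_config(spec, seed = 1)
report <- run_group_analysis(cfg)
print(report)
summary(report)
write_report_json(report, "report.json")
```

The README shows the printed output of a smaller configuration together
with a walk-through of what each number means.
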