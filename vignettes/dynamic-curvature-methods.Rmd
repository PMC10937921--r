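---
title: "Dynamic network curvature for treatment-response gene modules: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network curvature methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riccinet)
```

## The model

riccinet studies how gene expression *changes* co-vary across patients under
a paired intervention. Its object of analysis is a weighted graph whose
vertices are genes, whose admissible edges come from a protein-protein
interaction (PPI) topology, and whose weights are shifted Pearson
correlations of per-patient expression changes:

* change of gene g in patient p: `x_g(p) = norm_on(g, p) - norm_pre(g, p)`,
  scaled by the cross-patient standard deviation of gene g (sample, n - 1
  denominator) *without* centering, so the sign of regulation survives;
* edge similarity: `rho_shifted = (1 + rho) / 2 in [0, 1]`;
* edge transport cost: `1 / rho_shifted`, floored at `1 / eps`
  (`eps = 1e-6`) so perfectly anti-correlated edges remain finite;
* network metric `d`: all-pairs shortest paths over those costs.

Diffusion through the random-walk Laplacian `L = I - K^{-1} C_N` produces,
for every gene i and pseudotime `tau`, a probability distribution
`p_i = row i of exp(-tau L)` — the gene's neighborhood viewed through a lens
of scale `tau`. The per-edge dynamic Ollivier-Ricci curvature

```
kappa_ij(tau) = 1 - W1(p_i, p_j) / d_ij
```

compares the optimal-transport distance between the two lenses (ground cost
`d`) with the direct edge cost `d_ij`. Two regimes are analytic anchors: at
`tau = 0` the distributions are point masses, `W1 = d(i, j)`, and `kappa = 0`
exactly whenever the direct edge is itself a shortest path; as
`tau -> infinity` all distributions converge to the common stationary law
(proportional to the weighted degrees `K`), `W1 -> 0`, and `kappa -> 1`. In
between, edges inside tightly connected communities acquire high curvature
early while bridges lag or go negative — this separation is what the module
detection exploits.

Two conventions deserve emphasis:

* **Denominator vs ground cost.** The denominator `d_ij` is the *direct*
  edge cost, while the transport ground cost is the shortest-path metric.
  When a multi-hop path undercuts a direct edge, `kappa(0) > 0` for that
  edge; nothing is clamped, and the fixtures used for the "curvature starts
  at zero" checks are constructed so that every direct edge is a shortest
  path.
* **Critical scale.** `tau_crit` is the *first grid point* at which the
  99th percentile (linear interpolation between order statistics, R type 7)
  of all edge curvatures reaches 0.75 — grid-point semantics, not an
  interpolated crossing. The per-edge summary `kappa_bar_crit` integrates
  the trajectory over *linear* `tau` from 0 to `tau_crit` by the trapezoid
  rule, with the analytic point `(0, 0)` prepended; the log-spaced grid is
  simply an uneven partition. Whether to normalize the integral by
  `tau_crit` is exposed as a flag (`normalize`, default off — the literal
  integral); the choice rescales all weights equally and thus does not
  affect the Louvain partition, only the reported magnitudes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_score` | 700 | STRING combined-score cutoff ("high confidence"); the exact cutoff used at full scale is not recoverable, so it is configuration |
| `min_degree` | 5 | single-pass removal of low-degree vertices on the *initial* topology; deliberately not iterated to a k-core |
| `tau_n`, `tau_log10_range` | 101, [-2, 2] | diffusion grid |
| `percentile`, `kappa_threshold` | 99, 0.75 | critical-scale rule |
| `trunc_delta` | 1e-4 | cumulative small-mass support truncation before each transport solve; 0 disables it |
| `louvain_resolution`, `louvain_seed` | 1, 0 | community detection |
| `negative_weights` | "clamp" | negative integrated curvatures are clamped to 0 for the modularity objective (Newman modularity is undefined for negative weights); `"passthrough"` forwards raw weights for comparison with other implementations |
| `eps` | 1e-6 | similarity floor when inverting to cost |

Filter order is fixed: confidence, optional compartment sparsification,
degree, core-neighborhood expansion, largest component. The compartment
filter (drop edges whose annotated cellular-compartment label sets are
disjoint; genes without annotation are compatible with everything) is our
concretization of a literature procedure and is off by default.

## Exact optimal transport

The W1 solve is the computational core and is authored in C++ (no LP
library is involved):

* the **reference solver** poses each pair as a transportation problem over
  the truncated supports and solves it by successive shortest paths with
  node potentials on the dense bipartite residual graph — exact for any
  nonnegative ground-cost matrix;
* the **sweep solver** exploits that the pipeline's ground cost is the
  shortest-path metric of the network itself: mass shared between `p_i` and
  `p_j` transports for free, and the signed difference is routed as an
  uncapacitated min-cost flow over the network's own edges (Beckmann form),
  with each phase running one Dijkstra over reduced costs and a blocking
  flow over the tight arcs. Dual potentials are warm-started per edge from
  the previous scale (any potential vector the solver holds is 1-Lipschitz
  over the arcs, hence always a valid start), which keeps the Dijkstras
  shallow across the 101-scale sweep.

The two solvers agree to ~1e-12 on every fixture; that agreement is itself
asserted in the test suite, alongside a brute-force linear-programming
oracle (an off-the-shelf simplex applied to the full primal) on all graphs
with at most 8 vertices. An entropically regularized Sinkhorn backend
(log-domain, returning the unregularized cost of the entropic plan) is
provided for larger networks and agrees with the exact solver within 1% at
`eps = 0.005 * max(cost)` on the fixtures.

Numerical guards: reduced costs are clamped at zero against floating-point
residue (they are nonnegative in exact arithmetic — without the clamp,
Dijkstra can re-relax finalized nodes and corrupt the search tree); the
matrix exponential is computed by eigendecomposition of the symmetrized
similar matrix `K^{-1/2} C_N K^{-1/2}`, with tiny negative entries clipped
at zero and rows renormalized under a 1e-8 mass-error guard.

## What the synthetic generator emulates — and what it does not

The generator stands in for the real inputs with the statistical structure
the analysis assumes:

* **Topology**: a planted-partition graph, 120 genes in 6 equal blocks by
  default. The spec-level cohort conditions (43 matched patients plus 8
  pre-only and 15 on-only, gene-level noise sd 0.5, ~3 CR / ~6 PR / one NE
  patient with PD the largest group) mirror the melanoma cohort's shape at
  reduced scale. For the block densities we chose `p_in = 0.5`,
  `p_out = 0.05` once, by matching the analyzed study network's density
  (50,518 edges over 912 genes, ~0.12) at 120-gene scale: expected degree
  ~14.5, so the degree-5 filter stays the light touch it is at full scale.
  Markedly sparser settings put the expected within-block degree at the
  cutoff and shred the planted blocks before clustering ever sees them.
  Confidence scores are drawn uniformly on [700, 1000], emulating a
  high-confidence STRING export, so the planted densities remain the
  effective topology under the default cutoff.
* **Expression**: per patient and module a latent loading
  `lambda ~ N(0, 1)`; gene g in module m changes by
  `a_g * lambda[p, m] + N(0, noise_sd)` with amplitudes `a_g ~ U(0.5, 1.5)`
  — a rank-one block structure whose within-module correlation at the
  default noise is about 0.8. Pre-treatment values sit on per-gene
  baselines (log2 scale, mean 7); counts are `round(2^norm)` so the
  low-expression filter is exercisable, plus a handful of low-count decoy
  genes that the filter must remove.
* **Clinical**: survival exponential with hazard
  `h0 * exp(-beta * lambda[p, m*])` for a designated protective module
  `m*`; censoring exponential, calibrated to a target censored fraction;
  RECIST-like response from an ordinal model on the same loading (latent
  `1.5 * lambda + logistic noise` against cutpoints 3.5 / 2.0 / 0.0),
  which makes progressive disease the largest group and responders the
  smallest; one patient is relabeled NE to exercise the removal rule.

What it does **not** emulate: library-size and count-level noise (the rlog
normalization itself is out of scope — the pipeline consumes pre-normalized
values), batch effects, hub-dominated PPI degree distributions, and
correlated module loadings. Passing tests on this generator therefore
demonstrate that the machinery recovers the structure it assumes; they do
not certify behavior under real-data pathologies.

One practical consequence of the small panel: cross-sample **quantile
normalization** (pipeline default on, matching genome-wide practice)
assumes each sample's value distribution is comparable. On a 120-gene panel
in which entire modules shift coherently, that assumption fails and the
normalization erodes the clinical signal, so synthetic runs should set
`quantile_normalize = FALSE`. The flag also answers an ambiguity about
normalization order at full scale: the pipeline normalizes over all loaded
samples before subsetting to matched patients.

## Downstream statistics

Cox regression uses all module scores jointly with Efron tie handling; the
Kaplan-Meier / log-rank, Kruskal-Wallis and per-gene Wilcoxon analyses
target the module with the smallest Cox p-value (mirroring how a study
singles out its survival-associated module). Wilcoxon tests are exact for
combined n of at most 20 without ties, and continuity-corrected otherwise;
NE patients are removed and CR is pooled with PR before all response
analyses. Over-representation uses the upper-tail hypergeometric
`P(X >= k)` with `p = 1` at zero overlap, Benjamini-Hochberg adjusted; the
default universe is the analyzed network's vertex set. The within- vs
between-module curvature comparison uses the unequal-variance (Welch)
two-sample t-test and is skipped (means still reported) when either class
has fewer than two edges. Fully tied inputs are reported as no-evidence
(`H = 0`, `p = 1`) rather than NaN.

Two deliberate deviations from textbook shorthand: Benjamini-Hochberg
adjusted values are *not* idempotent under re-adjustment (re-running the
step-up procedure on adjusted values inflates them), so the suite asserts
order-equivariance and monotonicity instead; and a degenerate median split
(all scores equal) is an error, not a silent one-group comparison.

## Problem sizes and determinism

The default test suite runs everything at desk scale: geometry oracles on
graphs of at most 8 vertices (where exhaustive path enumeration, Bell-number
partition enumeration, and a simplex LP are feasible), a 7-vertex
two-clique fixture for curvature shape, and the full pipeline at 120 genes /
6 modules / 43 patients across 20 seeds for end-to-end recovery — about ten
minutes of compute in total, dominated by the 101-scale transport sweeps.
Every randomized component (generators, Louvain) is seeded explicitly;
reruns with one configuration are bit-identical, and the run manifest
records the configuration, seed, `tau_crit`, and module sizes needed to
replay a run. A full-scale replay on the original cohort (about 912 genes
and 50,000 edges) is supported by the same code paths — the Sinkhorn
backend and support truncation exist for exactly that regime — but requires
the external downloads and is not part of the test suite.

## Known limitations

* Louvain is a greedy heuristic; the returned partition is only guaranteed
  optimal on the small fixtures where the suite enumerates all partitions.
  Multi-restart consensus (`n_restarts`) mitigates but does not remove
  this.
* The similarity floor `eps` makes anti-correlated edges astronomically
  costly rather than infinite; ordering is preserved, but shortest paths
  through such edges are effectively forbidden.
* Support truncation (`trunc_delta`) perturbs each distribution by at most
  its truncated mass before renormalization; at the default 1e-4 the effect
  on kappa is far below every tolerance used here, and it can be disabled.
* With very slow-mixing networks (a single weak bridge), the top of the
  default grid (`tau = 100`) may not yet be numerically stationary to
  machine precision; the stationary-limit checks use well-mixed fixtures or
  larger scales.
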