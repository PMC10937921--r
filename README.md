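# riccinet

Multi-scale geometric analysis of treatment-response gene co-expression
networks, built around **dynamic Ollivier-Ricci curvature**.

## The problem

When paired tumor biopsies are profiled before and during a therapy
(for example, PD-1 checkpoint blockade in melanoma), the interesting signal
is often not any single gene but *groups of interacting genes whose
expression changes together* across patients. Correlation-network methods
such as WGCNA find such modules, but typically require arbitrary correlation
cutoffs. riccinet instead treats the protein-protein-interaction (PPI)
constrained correlation network as a geometric object and asks which edges
sit *inside* tightly information-sharing communities and which edges
*bridge* them.

## The method

1. **Expression changes.** For every patient with both a pre- and an
   on-treatment sample, compute the per-gene difference of normalized
   (log-scale) expression, on minus pre, and scale each gene by its
   cross-patient standard deviation *without centering* (the sign of the
   change is biology).
2. **Network.** Filter a STRING-style PPI topology (confidence cutoff,
   minimum initial degree 5), expand a curated core gene set to its PPI
   neighborhood, keep the largest connected component, and weight each
   surviving PPI edge by the Pearson correlation of its genes' scaled
   changes, shifted to a similarity `rho_shifted = (1 + rho) / 2`. Transport
   costs are `1 / rho_shifted`; the network metric `d` is all-pairs shortest
   paths (Dijkstra).
3. **Diffusion.** With the random-walk graph Laplacian
   `L = I - K^{-1} C_N` (where `C_N` is the shifted-correlation adjacency
   and `K` its row sums), simulate heat-kernel diffusion `D = exp(-tau L)`
   over 101 scales with `log10(tau)` spanning `[-2, 2]`. Row `i` of `D` is
   the neighborhood "lens" of gene `i` at scale `tau`.
4. **Curvature.** For each edge `(i, j)` and scale,
   `kappa_ij = 1 - W1(p_i, p_j) / d_ij`, where `W1` is the exact
   Wasserstein-1 optimal-transport distance between the two diffused
   distributions (ground cost = shortest-path metric) and `d_ij` the direct
   edge cost. Curvature starts at 0, ends at 1 when diffusion mixes
   completely, and in between separates within-community edges (high) from
   bridges (low or negative).
5. **Critical scale and modules.** `tau_crit` is the first scale at which
   the 99th percentile of edge curvatures reaches 0.75; each edge's
   curvature trajectory is integrated from 0 to `tau_crit`
   (`kappa_bar_crit`) and used as the modularity weight in Louvain
   clustering (resolution 1), yielding gene modules.
6. **Clinical association.** Per-patient module scores (mean scaled change
   over module genes) are tested against overall survival (multiple Cox
   regression, Kaplan-Meier on the median split with log-rank) and RECIST
   response (Kruskal-Wallis across CR/PR, SD, PD; per-gene Wilcoxon tests
   with Benjamini-Hochberg correction), and module gene lists against gene
   set collections (hypergeometric over-representation).

A fully synthetic generator (planted-partition PPI, latent per-module
patient loadings, proportional-hazards survival, ordinal RECIST-like
response) makes the entire pipeline testable end to end without any
download.

## Worked example

Simulate a 60-gene study with 3 planted modules in 30 patients, where the
third module's latent loading protects survival (`beta = 1`), then run the
whole pipeline:

```r
library(riccinet)

top  <- generate_topology(n_genes = 60, n_modules = 3, seed = 42)
expr <- generate_expression(top$topology, top$truth, n_patients = 30, seed = 43)
clin <- generate_clinical(expr$truth, beta = 1, seed = 44)

res <- run_pipeline(
  pipeline_config(tau_n = 51, quantile_normalize = FALSE, seed = 42),
  study = expr$study, clinical = clin$clinical, topology = top$topology,
  core_genes = synthetic_core_genes(expr$truth),
  collection = generate_gene_sets(clin$truth, seed = 45)
)
res
#> <pipeline_result> 45 genes / 200 edges; tau_crit = 2.089; 3 modules (sizes 17/15/13)
```

The three planted modules are recovered exactly, and integrated curvature
separates the edge classes sharply:

```r
res$within_between$summary
#> # A tibble: 2 x 3
#>   class   n_edges mean_weight
#> 1 within      167      0.718
#> 2 between      33     -0.0414    (Welch t = 22.7, p = 4.1e-25)
```

The Cox fit singles out the planted protective module (here detected as M2;
labels are renumbered by module size):

```r
tidy(res$cox)
#>   module estimate    hr std_error hr_low hr_high  p_value
#> 1 M1       -0.148 0.863     0.335  0.448   1.66  0.660
#> 2 M2       -1.40  0.245     0.409  0.110   0.547 0.000596
#> 3 M3        0.359 1.43      0.333  0.745   2.75  0.281

glance(res$km)     # Kaplan-Meier on the M2 median split
#>   module   cut chisq p_value
#> 1 M2     0.124  8.84 0.00294

res$kruskal        # responders change more than progressors
#>   module mean_crpr mean_sd mean_pd statistic    df p_value
#> 1 M2         0.653   0.316  -0.434      6.76     2  0.0340
```

A hazard ratio of 0.245 per unit score means patients whose module-2 genes
moved up on treatment die at roughly a quarter the rate; the Kruskal-Wallis
row shows the same module's score is highest in CR/PR responders and
negative in progressive disease. `autoplot(res$field, critical_curvature(res$field))`,
`autoplot(res$cox)` and `autoplot(res$km)` draw the trajectory, forest and
survival figures.

Note `quantile_normalize = FALSE`: the generator emits values already on a
common scale, and quantile normalization across a small gene panel in which
whole modules shift coherently would remove the very signal of interest (on
genome-wide data, the default `TRUE` is appropriate).

## Command line

A thin CLI over the same functions lives at `inst/cli/riccinet.R`:

```sh
Rscript inst/cli/riccinet.R simulate --dir run1 --seed 7
Rscript inst/cli/riccinet.R run-all  --dir run1 --seed 7
```
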