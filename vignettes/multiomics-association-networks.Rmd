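---
title: "Multi-omics association networks with plsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics association networks with plsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsnet)
```

## The problem

An organism's outward phenotype is mediated by several molecular layers —
gene expression in a tissue, the microbial community it hosts, circulating
cytokines, metabolite pools in serum and urine. These *internal phenotypes*
are usually analysed one at a time. `plsnet` implements a pipeline for
asking the cross-layer question: which features of one layer co-vary with
which features of another layer when the same animals are perturbed (here,
by diet), and which features sit at the crossroads of *all* layers?

The motivating design is a mouse feeding trial: 36 animals in six diet
groups (six protein sources, one of them — soy — serving as reference),
with five data blocks measured per animal where quality control permitted:
ileal transcriptomics, ileal microbiota composition, serum cytokines, and
serum and urine metabolomics. Block sizes are wildly unequal (tens of
thousands of transcripts versus 16 acyl-carnitines) and sample sets overlap
only partially. The pipeline is agnostic to the actual assays: any set of
positive sample-by-feature tables with a shared group factor works.

## Pipeline overview

1. **Differential screen** (per block). Values are log2-transformed and fit
   feature-wise to a cell-means linear model over the diet groups; each
   treatment is contrasted against the reference. Variances are moderated
   with the empirical-Bayes squeeze of `limma::eBayes()` and p-values are
   converted to FDR with Benjamini–Hochberg, per contrast. A feature is
   kept when its FDR drops below the per-block threshold in *at least one*
   contrast. Integrating only diet-responsive features focuses the networks
   on covariation induced by the shared perturbation.

2. **Pairwise sPLS integration.** For every pair of screened blocks
   \(X\) (\(n_x\) features) and \(Y\) (\(n_y\) features), sparse partial
   least squares in regression mode (5 components by default) selects
   covarying feature sets. The association matrix is
   \[
   Ma_{ij} = \begin{cases} \operatorname{cor}(X_i, Y_j) & \text{if } (i,j)
   \text{ is selected on some component} \\ 0 & \text{otherwise,} \end{cases}
   \]
   with Pearson correlations computed across all shared samples. Because
   the predictor/response designation is arbitrary for observational omics
   blocks, the fit is repeated with the roles swapped, giving
   \(Mb(Y,X)\), and the two orientations are combined as
   \[ M(X,Y) = Ma(X,Y) + Mb(Y,X)^{\mathsf T}, \]
   so a pair supported by both orientations with correlation \(r\) carries
   weight \(2r\).

3. **Dynamic dual thresholds.** Per network, only the strongest
   associations are kept: the upper threshold \(th_h\) retains the top 5 %
   of the positive weights, the lower threshold \(th_l\) the bottom 5 % of
   the negative weights, and the binary adjacency is
   \(A_{ij} = 1 \iff m_{ij} \ge th_h \lor m_{ij} \le th_l\). A
   *fraction*-based threshold adapts to each pair's correlation spread and
   avoids biasing edge counts toward larger blocks.

4. **Permutation null model.** Every feature row of both blocks is
   independently permuted over samples — marginal distributions are
   preserved exactly, all correlation is destroyed — and the full
   integration is re-run, recording the thresholds \((th_{lk}, th_{hk})\)
   per iteration \(k\). Locating the real \((th_l, th_h)\) in this null
   distribution (add-one-smoothed exceedance p) shows whether the retained
   edges could have arisen from chance correlations among that many
   features at that sample size.

5. **Merging, topology and hubs.** The \(\binom{B}{2}\) bipartite networks
   are merged into one undirected typed graph; nodes present in fewer than
   two of the contributing networks are dropped. The report covers degree,
   average local clustering, density \(2E/(N(N-1))\), connected components,
   and the characteristic path length defined as the *median* over nodes
   of each node's mean shortest-path distance (hop counts; the field's more
   common definition averages instead of taking the median — on the
   vertex-transitive graphs used in the tests the two coincide).
   *Connectivity hubs* are nodes whose neighbours span every data type
   other than their own.

## Worked example

```{r example}
pp <- data.frame(block_a = "cytokine", feature_a = 1:4,
                 block_b = "microbiota", feature_b = 1:4,
                 r = c(0.85, -0.85, 0.85, -0.85))
cfg <- sim_config(list(
  sim_block_spec("cytokine", 23, 36, prop_responsive = 0.5),
  sim_block_spec("microbiota", 40, 33, prop_responsive = 0.4),
  sim_block_spec("metabolomics_serum", 30, 36, prop_responsive = 0.5)),
  planted_pairs = pp, seed = 42)
sim <- generate_blocks(cfg)
res <- run_pipeline(sim$blocks, fdr_thresholds = 0.1,
                    null_iterations = 100, seed = 1)
res$pair_summary
res$topology
head(res$hubs[res$hubs$is_hub, ])
```

The null-model comparison per pair reports the exceedance p of each tail:

```{r null}
str(res$null_comparisons[["cytokine~microbiota"]])
```

## The synthetic-data generator

Real counterparts of four of the five blocks are not redistributable, so
the package ships a generator whose defaults mirror the study conditions:
6 diet groups × 6 mice, per-block sample retention of 33/33/36/36/28, and
desk-scale feature counts (200/50/23/41/16; the full assay sizes are one
`sim_block_spec()` away). On the log2 scale, a feature value is

> baseline + diet effect (responsive features only) + loading × shared
> latent factor (planted pairs only) + Gaussian noise,

and the output is exponentiated so the pipeline's own log transform is
exercised. Key choices:

* **Planted correlations are analytic.** For a target correlation `r`
  between features with noise SDs \(\sigma_a, \sigma_b\), the shared-latent
  loading solves \(r^2(t+\sigma_a^2)(t+\sigma_b^2) = t^2\) for
  \(t = \lambda^2\), so the generating model attains `r` exactly in
  expectation; \(|r| = 1\) is infeasible with positive noise and raises an
  error rather than being clipped. Planted features are excluded from the
  diet-responsive pool — a shared diet shift would add between-group
  covariance on top of the latent term and the closed form would no longer
  be exact.
* **Diet effects** shift a random non-empty subset of the non-reference
  groups by ±`effect_size` (default 1.5 log2 units = three noise SDs at
  the default `noise_sd = 0.5`: clearly detectable at 6 animals per group
  without being degenerate), so a responsive feature can be significant in
  one to five contrasts.
* **Dropout** removes samples uniformly at random per block, reproducing
  the partially overlapping sample sets of multi-assay designs.

The generator deliberately does *not* emulate assay physics: no microarray
intensity-dependent variance, no compositional closure or zero inflation
for the microbiota, no cell-level missingness, no batch structure. Passing
recovery tests therefore demonstrate the pipeline's correctness under its
own statistical assumptions (log-scale Gaussianity, exchangeable samples),
not robustness to real-world artefacts.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fdr_threshold` | 0.05 | per-block screen cut-off; practice ranges 0.001 (huge blocks) to 0.1 (small assays where every feature is informative) |
| `ncomp` | 5 | sPLS components; capped automatically at `min(n_x, n_y, n_shared − 1)` so small screened blocks stay integrable |
| `keep_x`, `keep_y` | all | per-component retained loadings; with full keep the dependency mask is all-ones and `M = 2 cor(X, Y)` |
| `fraction` | 0.05 | per-sign retained share of the non-zero weights |
| `n_iterations` | 200 (reference 1,000) | permutation iterations per pair |
| `min_networks` | 2 | merged-network membership filter; capped at `B − 1` |

## Numerical choices and degenerate inputs

* Loading vectors are sign-indeterminate; the entry of largest magnitude
  is made positive. NIPALS iterations stop when the loading change drops
  below `tol = 1e-9` (at most `max_iter = 500` iterations), initialised
  from the SVD of the cross-product.
* Sparsity keeps the `keep` largest-magnitude entries, soft-thresholding
  them by the largest dropped magnitude. Exact ties at the boundary shrink
  to zero (soft-thresholding cannot separate tied entries), so the
  non-zero count never exceeds `keep`; the kept set itself is defined by
  the stable order (magnitude descending, index ascending).
* Thresholds use the `ceiling(fraction × n)`-th order statistic per sign
  over the *non-zero* weights; boundary ties are all retained, matching
  the inclusive adjacency rule. A network with only one sign of weights
  gets a one-sided threshold (`±Inf` for the missing tail) with a warning.
* The exceedance p uses add-one smoothing, `(1 + #extremes)/(N_{it} + 1)`,
  so finite iteration counts never produce p = 0.
* Characteristic path length averages only over reachable nodes; on a
  connected network this choice is inert.
* Degenerate cases error loudly rather than silently: non-positive values
  at the log step (naming feature and sample), groups without samples,
  zero residual degrees of freedom, all-zero cross-products, zero-variance
  features inside dependent pairs, fewer than three shared samples.
* Duplicate merged edges (impossible among type-distinct pairwise
  networks, possible with user-supplied edge lists) collapse to the
  maximum-magnitude weight with provenance retained.

## Design decisions

* The membership filter counts *networks* a node appears in; counting
  neighbour *data types* instead is available via
  `filter_min_membership(variant = "types")`. The two differ only when two
  input networks join the same type pair, which cannot happen in the
  standard all-pairs run.
* Both blocks are permuted in each null iteration (permuting one would
  already break cross-block association; permuting both is the stronger,
  symmetric null). A per-feature permutation destroys within-block
  correlation too — the null is deliberately the harshest available.
* `proportion = 0.01` (the assumed share of regulated features) only
  parameterises the posterior log-odds of the moderated-t machinery; the
  pipeline filters on FDR, which is unaffected, so the value is stored for
  reporting only.
* With two blocks the ≥2-network filter would empty the merged graph
  (every node is in exactly one network), so `run_pipeline()` caps the
  filter at `B − 1`.

## Validation strategy and problem sizes

The test suite pins every operation to an independent oracle: hand-worked
OLS and Pearson examples, a brute-force step-up implementation against
`bh_adjust()`, the leading singular vectors of the scaled cross-product
against the unpenalised one-component sPLS fit (50 random 20 × 15 / 20 × 10
instances, agreement to 1e-8), the reference sPLS implementation in
mixOmics for the penalised case, and brute-force enumeration for hubs and
adjacency. Stochastic properties use the generator at desk scale: 12 × 12
blocks with ten planted |r| = 0.85 pairs for null-model separation (20
replicates × 200 iterations), 25 × 20 blocks for edge recall (50
replicates), 36-sample six-group designs for screen recall — sizes chosen
so the full suite exercises every claim in well under a minute per
property while keeping each check's power high.

## Limitations

* Edges are undirected correlations; no causal orientation is attempted.
* Within-block (same-type) associations are deliberately out of scope: the
  pairwise networks are strictly bipartite, which is also why their nodes
  all have zero clustering coefficient and why non-zero clustering emerges
  only in the merged graph.
* The per-block FDR thresholds and the sparsity levels are user choices;
  the package provides no cross-validated tuning.
* The null model validates *thresholds*, not individual edges; no per-edge
  FDR is computed.
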