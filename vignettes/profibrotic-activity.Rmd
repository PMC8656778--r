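---
title: "Scoring single-cell pathway activity and profibrotic phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring single-cell pathway activity and profibrotic phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scprofib)
```

## The problem

Fibrogenic (ECM-producing) cells are a minority population scattered across
many cell types. Cluster-level differential expression cannot see them: a
cluster averages over active and inactive cells alike. `scprofib` instead
asks, for every individual cell, "how high do the genes of one pathway sit
in this cell's expression profile?" — a single-sample gene-set question
posed at single-cell resolution.

## The model

### Preprocessing

Cells with fewer than 400 UMIs, fewer than 200 detected genes, or more than
20% mitochondrial UMIs are removed (`qc_filter()`; boundaries inclusive —
only strictly worse cells go). Counts are normalized to a common library
size and log-transformed: `log1p(count / total * 10^4)`
(`normalize_library_size()`). The 10,000 scale factor is the conventional
counts-per-ten-thousand choice; NES is invariant to it because only
within-cell ranks matter downstream. Batch correction and cell-cycle
regression are deliberately out of scope: the pipeline accepts an
externally corrected matrix and otherwise runs a no-op, since the scoring
step does not depend on their internals. `cluster_cells()` provides the
clustering hook — PCA (50 components by default) followed by Louvain
community detection on a 15-nearest-neighbour graph with a fixed seed; any
externally supplied labels can be used instead.

### Within-cluster standardization

Each gene is standardized to mean 0 and unit variance *within each
cluster* (`standardize_within_cluster()`). This is the step that makes the
method work on an atlas: a cell's gene ranks are computed relative to
transcriptionally similar cells, so cell-type identity genes do not drown
the pathway signal, and residual annotation biases are absorbed by the
cluster structure. We use the population (N-denominator) standard
deviation; the choice is configurable (`sd_type = "sample"`) and cannot
change any rank, hence any NES — only the Z magnitudes. Zero-variance
genes get Z = 0, and a single-cell cluster is all-zero with a warning.

### The MWW-GST statistic

Each cell's genes are ranked by Z-score with the **largest Z receiving the
largest rank** G. The rank-direction convention is fixed by the semantics
of the score: with m pathway genes at the top of the profile, T (the sum
of the pathway genes' ranks) is maximal, U = nm + m(m+1)/2 − T is 0, and

$$\mathrm{NES} \;=\; 1 - \frac{U}{mn} \;=\; 1,$$

"maximum activation". NES equals the fraction of (in-set, out-set) gene
pairs in which the in-set gene outranks the out-set gene — the
Mann-Whitney AUC — and the test suite verifies the formula against
exhaustive pair counting at machine precision.

Sparse single-cell matrices guarantee massive ties (most Z-scores in a
cluster are the standardized zero). Ties take average ranks, and the
p-value uses the one-sided ("greater"; activity is one-directional by
construction) normal approximation with the standard tie-corrected
variance and a continuity correction. Exact enumeration is infeasible at
G ≈ 20,000 genes, and the normal approximation is excellent at these m
and n.

### Calling active cells

p-values are adjusted across cells with Benjamini–Hochberg, one family per
pathway, and a cell is active iff NES > 0.3 **and** q < 0.05, both strict:
(NES, q) = (0.30, 0.001) is *not* active. The per-pathway FDR scope is a
documented choice — adjusting across pathways too would mix families of
very different sizes; scoring additional pathways therefore never changes
the ECM calls.

## Signatures, co-activity, validation

`extract_degs()` compares active vs inactive cells of one cell type with a
two-sided Wilcoxon rank-sum test per gene (consistent with the rank-based
core; no distributional assumptions on log-normalized sparse data), BH
across genes, q < 0.05 retained. The log-fold change uses a pseudocount:
`ln(mean_active + 1e-9) − ln(mean_inactive + 1e-9)`. When the active
population is a whole annotated subcluster, `reference_cell_type` selects
the explicit counterpart instead of the per-cell flags. `ora_enrich()`
annotates a signature by hypergeometric over-representation with strict
reporting gates (set size > 15 within the universe, overlap ratio > 0.10,
q < 0.05); the universe is the detected genes of the dataset, not the
genome, to avoid detection-bias inflation.

`coactivity_test()` crosses ECM activity with another pathway's activity
in a 2×2 table and computes the one-sided (enrichment) Fisher exact
p-value — one-sidedness is a documented choice; co-activity is a positive
association by definition. `build_network()` keeps pathways at q < 0.05,
orders them lexicographically by (q ascending, prevalence descending) —
a fixed resolution of "both significance and proportions" — takes the top
10% with a **ceiling** (so one significant pathway still yields a node)
capped at 10, and links two pathways when more than 80% (strict) of the
ECM-active cells are active for both, normalized by the cell type's total
ECM-active count (the same denominator as prevalence; Jaccard would mix
denominators).

`signature_nes()` scores a signature in an independent dataset:
standardization within *cell type* (validation datasets carry curated
annotations rather than de novo clusters), then the same rank → MWW-GST
per cell. Raw NES distributions are compared across conditions — the
active-call thresholds play no role in validation. Cross-species symbols
map through a user-supplied table with case-insensitive identity as the
fallback, which covers most human/mouse pairs without an ortholog service.
`compare_conditions()` runs all pairwise two-sided Wilcoxon tests with BH
across pairs.

## Bulk projection and survival

`build_marker_matrix()` assembles the phenotype marker file: rows are the
union of all cell types' DEGs, columns are cell type × (active, inactive)
phenotypes, values are mean *linear-scale* expression (expm1 of the
log-normalized values — means of logs would not mix linearly in a bulk
sample). `write_cibersortx_signature()` emits the exact tab-delimited
upload dialect (gene column `GeneSymbol`) so the matrix can also be fed to
an external deconvolution service.

`score_bulk()` is a transparent stand-in for such services: per sample,
non-negative least squares of the marker-gene vector on the phenotype
columns, coefficients normalized to sum to one ("relative mode"). It makes
no claim to reproduce support-vector deconvolution; it is exact on
noiseless mixtures and accurate (MAE < 0.05 at 5% multiplicative noise) on
simulated ones, which is what the downstream survival logic needs. The
profibrotic score of a cell type is its active column's coefficient.

`km_quartile_analysis()` splits samples at the 25th/75th percentiles of a
score (type-7, linear-interpolation quantiles) into a low group (≤ Q1) and
a high group (≥ Q3), excludes the interquartile middle, and compares
Kaplan–Meier curves with the log-rank test at p < 0.05. We read the
two-group construction as Q1-vs-Q4 — the extreme-quartile contrast that a
25th/75th split implies; a dichotomization at both cut points would leave
the middle samples in both groups at once.

## What the simulators emulate

`simulate_sc()` draws negative-binomial UMI counts (the standard model for
droplet data) from per-cluster gene-mean profiles with log-normally
varying depth, and plants an active subpopulation — 30% of one cluster
whose pathway-gene means are multiplied by exp(δ). Defaults: 2,000 genes,
3,000 cells, 5 clusters, a 100-gene pathway, δ = 2, dispersion 2, mean
depth 2,000 UMIs — a down-sampled but realistically sparse droplet
experiment (mean ≈ 1 count/gene/cell) sized so the full pipeline runs in
seconds. Tests in this package run the same generator at 100–3,000 cells
and 200–2,000 genes depending on the property checked.

The generator does **not** emulate batch effects, doublets, ambient RNA,
gene-gene correlation beyond cluster structure, or annotation errors.
Passing tests therefore demonstrate the pipeline's statistical correctness
and its recovery behaviour under the stated generative model — not
robustness to artefacts that upstream tools are expected to remove.

`simulate_bulk()` draws Dirichlet mixture weights over the phenotype
columns and adds multiplicative log-normal noise; `simulate_survival()`
draws exponential event times with hazard `baseline × exp(β · score)` and
independent exponential censoring. All generators are pure functions of
(config, seed).

## Numerical choices and degenerate inputs

- Gene symbols are uppercased and trimmed on entry; matching is
  case-insensitive everywhere.
- A gene set absent from the matrix is an error in `scssa()` and a
  `scorable = FALSE` flag in `mww_gst()` — never a silent NES of 0.
- Zero-variance genes standardize to 0; all-tied profiles get p = 1.
- NNLS coefficients that sum to 0 (an all-zero sample) yield NA scores.
- Degenerate score quantiles (25th = 75th percentile) are an error in the
  survival split, as is an empty group.
- Fisher p-values are computed from the hypergeometric tail directly;
  tests verify equality with exhaustive enumeration for all 2×2 tables
  with N ≤ 40 and with `fisher.test` on random tables.

## Limitations

NES compares a pathway against the rest of the transcriptome within one
cell, so heavy dropout compresses ranks and shrinks NES toward 0.5; the
0.3/0.05 calling rule is calibrated for sparse data but remains a fixed
threshold, not an adaptive one. The quality of within-cluster
standardization bounds the quality of the scores: badly merged clusters
blur the reference distribution. The bulk projection is a least-squares
phenotype-fraction estimate and inherits the usual caveats of linear
deconvolution (collinear phenotype profiles inflate variance). Survival
stratification discards the interquartile half of the cohort by design,
trading power for contrast.
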