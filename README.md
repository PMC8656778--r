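# scprofib

Single-cell pathway activity scoring and profibrotic phenotype analysis.

Profibrotic cells — cells actively transcribing the extracellular-matrix
(ECM) gene program — appear early in fibrosis and shape the tumor
microenvironment, but they are rare, scattered across cell types, and
invisible to cluster-level analyses. `scprofib` finds them by scoring the
activity of a gene pathway **in every single cell** and carries the result
through a complete downstream analysis: active-cell calling, cell-type
signature extraction, co-active pathway networks, cross-condition
validation, projection into bulk samples, and survival stratification.

## The statistic

Within each cell cluster, expression of every gene is standardized to a
Z-score, and each cell's genes are ranked by Z (largest Z → rank G). For a
pathway with m genes present in the profile and n genes outside it, the
Mann-Whitney-Wilcoxon gene-set test (MWW-GST) computes

```
T   = sum of the ranks of the pathway genes
U   = nm + m(m+1)/2 − T
NES = 1 − U / (mn)
```

NES ∈ [0, 1] estimates the probability that a random pathway gene outranks
a random non-pathway gene in that cell: ≈0.5 means no signal, →1 means
maximal activation. A one-sided tie-corrected normal approximation gives a
p-value per cell; Benjamini–Hochberg adjustment runs across cells, and a
cell is called **pathway-active** when NES > 0.3 and q < 0.05 (both strict).

Downstream, active-vs-inactive differential genes (Wilcoxon rank-sum, BH),
Fisher exact co-activity tests between pathways, non-negative least-squares
projection of the phenotype marker matrix into bulk samples ("relative
mode": per-sample coefficients are non-negative and sum to 1), and
quartile-split Kaplan–Meier analysis (Q1 vs Q4, log-rank test) complete the
pipeline. Everything is testable offline through built-in negative-binomial
single-cell, bulk-mixture and survival simulators with planted truth.

## Worked example

```r
library(scprofib)
sim <- simulate_sc(sim_config(seed = 7))   # 2,000 genes x 3,000 cells,
                                           # 100-gene pathway planted in
                                           # 30% of one cluster (delta = 2)
flt <- qc_filter(sim$mat, sim$ann)         # >=400 UMIs, >=200 genes, <=20% mito
nrm <- normalize_library_size(flt$mat)     # log1p CP10K
fit <- scssa(nrm, clusters = flt$ann$cluster, gs = sim$pathway)
fit
#> scssa fit: pathway 'SIM_PATHWAY' (m = 100 in-set, n = 1900 out-set genes)
#>   3000 cells scored; 181 active (NES > 0.3 & q < 0.05)

truth <- sim$truth[match(flt$ann$obs_id, sim$truth$obs_id), ]
res <- as.data.frame(fit)
mean(res$active[truth$planted])    #> 1.000   (sensitivity on planted cells)
mean(res$active[!truth$planted])   #> 0.0004  (false-positive rate)

head(res[order(-res$NES), c("obs_id", "NES", "p", "q", "active")], 3)
#>        obs_id       NES            p            q active
#> 62  CELL00062 0.8115895 3.577971e-26 1.073391e-22   TRUE
#> 163 CELL00163 0.8054368 3.172798e-25 4.759197e-22   TRUE
#> 32  CELL00032 0.7902263 5.820196e-23 5.820196e-20   TRUE
```

The 181 called cells are almost exactly the 180 planted ones: the planted
subpopulation over-expresses the pathway genes e²-fold, which lifts its NES
distribution (mean ≈ 0.69) clear of the background (≈ 0.48).

From here, `extract_degs()` pulls the active-vs-inactive signature per cell
type, `coactivity_records()` + `build_network()` assemble the co-active
pathway network, `signature_nes()` + `compare_conditions()` validate a
signature across conditions, and `build_marker_matrix()` → `score_bulk()` →
`km_quartile_analysis()` take the signature into bulk samples and survival.
See `vignette("profibrotic-activity")` for the full methods account.

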