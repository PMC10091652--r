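# snfsubtypes

Molecular subtype discovery for heterogeneous patient cohorts from
multi-cell-type single-nucleus RNA-seq, by similarity network fusion of
gene and gene-set expression.

## What it does, and for whom

Neurodevelopmental and psychiatric cohorts (the package's running example
is an autism case/control brain cohort) are molecularly heterogeneous:
diagnosis-wide differential expression averages over patient groups with
distinct biology. This package implements a subtype-first workflow for
computational biologists:

1. **Per-cell gene-set scoring.** Expression of each cell is summarised at
   a second level — gene sets — with a GSVA-style statistic: a Gaussian
   kernel CDF transform per gene, the symmetric rank statistic
   r = |p/2 − rank|, and a weighted Kolmogorov–Smirnov-like random walk
   whose score is the maximum positive plus minimum negative deviation.
2. **Two-level similarity network fusion (SNF).** Per cell type and per
   modality (genes; gene sets), patient–patient affinity matrices
   W_ij = exp(−d_ij/(μ ε_ij)) with locally scaled ε are fused by iterative
   cross-diffusion P_v ← S_v P̄ S_vᵀ through K-nearest-neighbor kernels
   (K = 3, T = 100); the two modality-level networks are fused again into
   the final patient network.
3. **Spectral clustering with model selection.** Normalized-Laplacian
   spectral clustering; the number of subtypes is chosen by the eigen-gap,
   with a rotation-cost curve and affinity-based silhouettes as
   diagnostics.
4. **Subtype-specific differential expression.** Genes: a two-part hurdle
   model (logistic detection + Gaussian expression) with likelihood-ratio
   tests, covariate-adjusted (detection rate, age, sex, RIN, PMI, region,
   batch, ribosomal fraction). Gene sets: an empirical-Bayes moderated
   linear model. A feature is subtype-specific when it is differential
   both versus the other subtypes and versus controls, at
   |log2FC| ≥ 0.14 and FDR < 0.05.
5. **Downstream characterisation.** Unique/common feature partition and
   discordant-direction screening; clinical association (combined ADI-R
   rank score, patient-level fold changes, Pearson + Fisher's method,
   per-category rank t-tests); hypergeometric risk-gene enrichment;
   cross-dataset subtype correspondence against a bulk cohort; and PLS-DA
   subtype prediction under three data-splitting schemes with
   micro/macro/weighted F1.

A seeded synthetic cohort generator (`simulate_cohort`) plants subtypes,
DE genes, coordinated gene-set shifts, covariates and linked clinical
scores, so the entire pipeline is testable end to end without any data
download. See the vignette in `vignettes/subtype-discovery-methods.Rmd`
for the models, assumptions and numerical conventions.

## Worked example

```r
library(snfsubtypes)

cfg <- sim_config(seed = 1)          # 15 cases (subtypes 6/4/5), 16 controls,
co  <- simulate_cohort(cfg)          # 3 cell types, 500 genes, 50 gene sets
write_cohort(co, "data/cohort")

res <- run_pipeline(pipeline_config("data/cohort", "results/pipeline", seed = 1))

res$assignment$k
#> [1] 3
adjusted_rand_index(res$assignment$labels[names(co$truth$subtype_of_patient)],
                    co$truth$subtype_of_patient)
#> [1] 1
round(c(genes = res$assign_genes$silhouette,
        sets  = res$assign_sets$silhouette,
        final = res$assignment$silhouette), 2)
#> genes  sets final
#>  0.92  0.94  0.83
nrow(res$de$specific_genes)
#> [1] 267
res$prediction[["CT1.random_cells"]]$macro_f1
#> [1] 0.978511
```

The pipeline selects three subtypes by the eigen-gap, recovers the planted
patient partition exactly (adjusted Rand index 1), finds the planted
subtype-specific DEGs, and a PLS-DA classifier on those DEGs separates the
subtypes' cells with macro F1 ≈ 0.98 under a stratified 7:3 split. The
numbered scripts under `analysis/` run the same stages as a narrated
workflow (simulation → subtype discovery → bulk correspondence →
prediction), writing tables under `results/`.

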