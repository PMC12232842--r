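# nichecomm

Does the tissue microenvironment of a cell type change its transcriptional
profile, and do ligand–receptor communication predictions agree with where
cell types actually sit in space?  `nichecomm` implements, as a tested and
reusable R pipeline, the analysis framework needed to ask both questions on
paired single-cell RNA-seq + spot-level spatial transcriptomics data — and a
synthetic data generator with planted ground truth so that every stage can
be validated without any external download.

## What the pipeline computes

Given a gene×cell count matrix, a spot grid with coordinates, cell type
annotations, a cell→spot assignment (computed internally or ingested from
an external mapper) and a ligand–receptor database:

1. **Spatial assignment.** Either capacity-constrained expression matching
   — cost `1 − cor(cell, spot)` over highly variable genes, solved as an
   exact minimum-cost assignment with per-spot capacities estimated from
   spot totals — or nearest-spot snapping of coordinate-valued mappings.
2. **Spatial stratification** of a focal cell type into groups, by
   histological region labels or by spatially weighted gene co-expression
   modules: a Gaussian kernel on cell–cell distances smooths expression,
   modules come from average-linkage clustering of the smoothed gene–gene
   correlation (distance `1 − r`), and each cell is labeled by its highest
   bin-matched module activity score.
3. **Niche-dependent expression.** Pairwise cosine distances between
   normalized profiles within/between groups compared by Kolmogorov–Smirnov;
   differential expression by Wilcoxon rank-sum (BH-adjusted, flagged at
   linear fold change > 1.5 and adjusted p < 0.05) and by a pseudobulk
   negative-binomial Wald test on 3 summed pseudoreplicates per group
   (flagged at |log2FC| > 1.5 and adjusted p < 0.05).
4. **Communication inference.** A CellPhoneDB-style permutation test: the
   score of (sender, receiver, interaction) is the mean of the ligand
   complex value in the sender and the receptor complex value in the
   receiver (complex value = minimum subunit mean), gated on every subunit
   being expressed in > 10% of the group's cells; p-values come from
   permuting group labels over all cells, `p = (1 + #{perm ≥ obs}) / (n + 1)`.
   Equal-size subsampling (10 datasets) controls for group-size effects.
5. **Colocalization and concordance.** A binary spot×type presence matrix
   (1 if ≥ 1 cell of the type maps to the spot) yields pairwise Jaccard
   similarities `J(A,B) = |A∩B| / |A∪B|`; the headline statistic is the
   Spearman correlation, per focal group, between its per-partner counts of
   significant interactions and its per-partner Jaccard values.

The synthetic generator (`generate_dataset()`, presets
`breast_like` / `layered_like` / `node_like`) plants region structure,
1–9 cells per spot, negative-binomial signatures, niche-shifted genes of
stated log2 fold change, and ligand–receptor activity that is either
restricted to spatially colocalized type pairs (*coupled*) or independent
of space (*decoupled*), with all ground truth returned alongside the data.

## Worked example

```r
library(nichecomm)
options(nichecomm.verbose = FALSE)
res <- run_pipeline(pipeline_config("breast_like", seed = 1))
str(res$summary$spearman)
#> List of 2
#>  $ Cancer@R1:List of 3
#>   ..$ rho: num 0.86
#>   ..$ p  : num 0.00294
#>   ..$ n  : int 9
#>  $ Cancer@R2:List of 3
#>   ..$ rho: num 0.934
#>   ..$ p  : num 0.000223
#>   ..$ n  : int 9
res$summary$n_significant_interactions
#> [1] 44
head(res$counts[res$counts$focal == "Cancer@R1", ], 4)
#>       focal   partner count
#> 1 Cancer@R1     Bcell     0
#> 3 Cancer@R1       CAF     7
#> 5 Cancer@R1 Cancer@R1     0
#> 7 Cancer@R1 Cancer@R2     0
```

The generator planted 22 active ligand–receptor interactions between the
focal tumor-like cells and their four spatially colocalized partner types
(3, 4, 8 and 7 for T cells, myeloid, endothelial and CAF-like cells); the
permutation test recovers them (44 = 22 edges × 2 focal sender groups) and
assigns zero counts to the four spatially disjoint types, so counts and
Jaccard colocalization rank together: rho ≈ 0.86/0.93 for the two focal
groups.  Re-running with `coupling_mode = "decoupled"` elevates the same
interactions everywhere regardless of space and the correlation collapses
(|rho| ≲ 0.2) — communication counts no longer carry spatial information,
the negative control for the concordance analysis.

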