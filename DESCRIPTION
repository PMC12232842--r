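Package: nichecomm
Title: Niche-Dependent Expression and Spatially Informed Cell-Cell
    Communication Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether the tissue microenvironment (spatial
    niche) of a cell type changes its transcriptional profile and whether
    predicted ligand-receptor communication agrees with spatial
    colocalization.  Provides readers and preprocessing for paired
    single-cell and spot-level spatial transcriptomics data, a synthetic
    data generator with planted ground truth, capacity-constrained
    cell-to-spot assignment, spatial stratification of a focal cell type
    (by region labels or spatially weighted co-expression modules),
    cosine-distance and differential-expression comparisons between
    spatial groups (Wilcoxon and pseudobulk negative-binomial Wald),
    permutation-based ligand-receptor tests with mean scoring, Jaccard
    spot-colocalization statistics, and the rank-correlation concordance
    between communication counts and colocalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
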