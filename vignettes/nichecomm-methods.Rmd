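---
title: "Methods: niche-dependent expression and communication-colocalization concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche-dependent expression and communication-colocalization concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nichecomm` asks two linked questions about paired single-cell and
spot-level spatial transcriptomics data: does a cell type's spatial niche
detectably change its transcriptional profile, and do ligand–receptor (LR)
communication predictions made from expression alone agree with where cell
types actually colocalize?  This vignette documents the statistical
machinery, the choices behind every tunable parameter, what the synthetic
benchmark does and does not emulate, and the package's known limits.

## Data model

The substrate is a gene×cell matrix of non-negative integer counts with an
optional log-normalized layer (`gem`), a slide of spots with coordinates
and optional region labels (`slide`), a `cell_id → cell_type` annotation,
a `cell_id → spot_id` assignment, and an LR database whose multi-subunit
complexes are `_`-joined gene ids.  Normalization is counts-per-`target_sum`
(default 10,000) followed by `log1p`, natural log by default with a log2
option because expression-matching mappers conventionally work on
log2-normalized data; both appear in the field and the choice is explicit
configuration, not a hidden constant.  Cells with zero totals are kept as
zero columns (with a warning) so that downstream set sizes stay
predictable; a drop option exists.

Spot quality control follows standard Visium-scale practice: spots are kept
when their totals lie strictly inside `(5000, 35000)` and their
mitochondrial percentage (genes matched by the configurable prefix `MT-`)
is at most 20%; genes detected in fewer than 10 remaining spots are
dropped.  The synthetic presets override the count window (200 to 1e6)
because simulated spots carry a few hundred to a few thousand counts.
Applying the spot filter twice is a no-op unless removing low-prevalence
genes pushes a spot's total across the window boundary — possible in
principle, not observed on data with any margin between spot totals and the
thresholds.

Highly variable genes are ranked by binned normalized dispersion: per gene,
`var/mean` of `expm1(norm)`, z-scored within 20 equal-frequency bins of
mean expression, ties at the cutoff broken by lexicographic gene id so the
selection is fully deterministic.

## Cell-to-spot assignment

External mappers are first-class inputs: any two-column
`cell_id → spot_id` table can be ingested.  The built-in mapper is a
deliberately simple, fully specified stand-in for them: per-spot capacities
are estimated proportionally to spot totals
(`max(1, round(n_cells · total_i / Σ totals))`, deficits added to the
largest spots), the cost of placing a cell in a spot is `1 − Pearson`
(optionally Spearman) correlation of their normalized profiles over a
configurable gene subset (spot-matrix HVGs by default), and the
capacity-expanded rectangular assignment problem is solved exactly by
shortest augmenting paths with dual potentials — the same algorithm family
the field's optimization-based mappers use.  Ties in the cost resolve
toward the smallest column index, i.e. (cell, spot) input order, so results
are reproducible.  Exact solving is O(n²m) and fine at desk scale
(hundreds of cells); a greedy flag exists for large instances and announces
that its total cost is not guaranteed optimal.  Coordinate-valued mappings
are converted with nearest-spot Euclidean snapping (ties to the
lexicographically smallest spot id).

## Spatial stratification of a focal type

Two routes produce the `≥ 2` spatial groups the comparative stages need.
With region labels, each focal cell inherits its spot's label (unlabeled
spots are excluded with a warning).  Without them, the package uses a
spatially weighted co-expression stratification: a Gaussian kernel
`K_ij = exp(−d_ij²/(2σ²))` on Euclidean cell–cell distances, row-normalized
and used to smooth each gene's expression vector before computing the
gene–gene Pearson correlation.  Smoothing-then-correlating was chosen over
directly kernel-weighting the covariance because its σ→0 limit is exactly
the plain correlation (a testable anchor; `sigma = 0` uses the identity
kernel) and it avoids degenerate normalizations.  The default σ is the
median pairwise distance between the focal cells — scale-free and
reasonable for both lattice and continuous coordinates.  Modules come from
average-linkage hierarchical clustering of `1 − r`, cut at a fixed `k`
(default 3, the value used when stratifying a cortical layer into
inner/middle/outer bands); clusters below `min_size` (default 10 genes) are
dropped.  This is an explicit simplification of WGCNA-style detection — no
soft-thresholding power, no topological overlap, no dynamic tree cut.
Cells are then scored per module as mean module-gene expression minus the
mean of a control pool drawn per module gene (100 controls each, seeded)
from the same average-expression bin among 24 bins — the widely used
control-gene module-score convention — and labeled by their highest score,
ties toward the lexicographically first module name.  Because controls are
drawn from the module genes' own expression bins, a planted shift is
recovered slightly attenuated when module genes dominate their bins; the
tests quantify this.

Which groups to contrast downstream is configuration, not automation: the
pipeline takes the two largest groups by default (deterministic tie-break
by name).

## Niche-dependent expression

Global profile comparisons use pairwise cosine distances
(`1 − x·y/‖x‖‖y‖`) over all QC-retained genes of the normalized layer by
default (an HVG-restricted mode exists; the literature is silent on the
scope, so it is explicit config).  Within-group, between-group and
focal-versus-background distance distributions are compared with the
two-sample Kolmogorov–Smirnov test (asymptotic p).

Single-gene tests come in two flavors with deliberately different
significance gates, both of which appear in practice:

* **Wilcoxon rank-sum** per gene on normalized values (normal approximation
  with tie correction, two-sided), BH correction, flagged at **linear**
  fold change > 1.5 and adjusted p < 0.05.  The fold change is
  `log2((mean expm1 g1 + ε)/(mean expm1 g2 + ε))` with `ε = 1e−9` so it is
  total on all-zero genes.
* **Pseudobulk NB Wald**: cells of each group are randomly partitioned
  (seeded) into 3 near-equal pseudoreplicates whose raw counts are summed;
  size factors by median-of-ratios (total-count ratio fallback when > 90%
  of gene-wise geometric means vanish); per-gene dispersion by method of
  moments on normalized counts, floored at 1e−8; a two-group NB log-link
  GLM with size-factor offsets gives the Wald z; BH; flagged at **log2**
  fold change > 1.5 and adjusted p < 0.05.  This is a documented
  simplification of full bulk-style NB machinery — no dispersion shrinkage
  toward a trend, no LFC shrinkage, no independent filtering — and parity
  with those methods is a non-goal.  With three replicates per group the
  method-of-moments dispersion is noisy and raw Wald p-values run
  anti-conservative; the fold-change gate plus BH keeps the flagged null
  fraction near zero, which is the operative false-positive control.

The linear-vs-log2 asymmetry of the two 1.5 thresholds is intentional and
kept as two separate configuration keys; the source conventions differ
between the two testing traditions and silently unifying them would change
results.

## Permutation LR test

For each ordered (sender, receiver) pair of groups with at least
`min_cells = 10` cells and each interaction, the observed score is
`(ligand value in sender + receptor value in receiver)/2`, where a
complex's value is the minimum of its subunit mean normalized expressions,
and the pair is gated on every subunit being expressed in more than
`expr_prop = 0.1` of the group's cells.  Group labels are permuted over
*all* cells (mirroring cluster-label permutation semantics) `n_perm = 1000`
times and `p = (1 + #{perm ≥ obs})/(n_perm + 1)` — the add-one convention
never returns 0 and makes the null rejection rate at α = 0.05 equal
50/1001 ≈ 0.05 by construction.  Gated-out triples carry p = 1.  Autocrine
pairs are scored by the same rule.  An exhaustive mode enumerates all label
arrangements for two groups and is the package's own oracle in tests.
Cells are put in canonical (sorted id) order before drawing permutations so
p-values do not depend on input column order.  Equal-size subsampling (all
groups downsampled without replacement to the minimum group size, 10
distinct datasets by rejection sampling capped at 1000 attempts) reruns the
test to control for group-size artifacts.

Significant-interaction counts per focal group and partner sum both
directions by default (`sender_only`/`receiver_only` exist) because figure
conventions in the field report one count per pair without stating
directionality.

## Colocalization and concordance

The presence matrix scores a spot 1 for a label if at least one cell with
that label maps there; focal spatial groups replace their parent type as
separate columns, and the spot universe is the QC-retained spots.  Jaccard
similarity of the presence columns measures colocalization; the
empty-versus-empty case is defined as 0 and flagged rather than 1, to avoid
spurious perfect colocalization of absent types.  Concordance is the
Spearman correlation (average ranks; p by the t approximation with n − 2
degrees of freedom, adequate at the 8–15 partner counts involved) between a
focal group's per-partner significant-LR counts and its per-partner Jaccard
values, excluding the group itself and including the sibling focal group by
default.

## The synthetic benchmark

`generate_dataset()` draws a square-lattice spot grid (hexagonal geometry
adds nothing to set-based colocalization logic), per-spot capacities
uniform on 1–9 (the Visium-scale span), and places cells one at a time with
probability proportional to remaining capacity times the type's abundance
weight in the spot's region.  Counts are negative binomial with variance
`μ + μ²/θ` and a single global θ = 8 — mid-range single-cell
overdispersion.  Each type carries 10 exclusive marker genes at a log-mean
offset of 1.6 (≈ 5-fold, a clear but not caricatural signature); niche
effects multiply planted genes' means by `2^log2fc` for focal cells whose
true spot lies in the named region; spot profiles are the sums of their
cells' counts plus Poisson(0.1) ambient counts per entry.

Planted LR activity elevates per-interaction ligand/receptor genes from a
near-zero baseline mean (0.01) to 3 in the sender/receiver type.  The
near-zero baseline is what makes partner specificity testable: the
expressed-fraction gate (> 0.1) silences an interaction wherever the
receptor is not genuinely expressed, exactly the mechanism by which
CellPhoneDB-style tests separate partners.  In `coupled` mode an edge is
active only if its two types share at least one true spot — the same
predicate the pipeline later estimates; in `decoupled` mode every planted
edge is active regardless of space.

The `breast_like` preset stratifies a tumor-like focal type across two
regions with four colocalized partners of graded abundance (so their
Jaccard values are ordered) and four types confined to a third region
(Jaccard exactly 0 under the true assignment).  The planted per-partner
edge counts (3, 4, 8, 7 for the colocalized partners; 2, 5, 6, 9 for the
disjoint ones) were chosen so that, with the sibling focal group included
in the partner list at count 0 and Jaccard 0, the rank covariance between
counts and the expected colocalization ordering is ~0: the decoupled run is
then a stable negative control by construction, while coupling zeroes the
disjoint partners' counts and forces a strong positive rank correlation.
`layered_like` spans a focal type over three contiguous bands with
band-specific neighbors and three 15-gene band programs at log2FC 2 —
layer-marker-strength signals — as the substrate for the co-expression
stratification.  `node_like` concentrates a fibroblast-like type into one
dominated region (> 50% of its cells).

What the generator does **not** emulate: realistic gene–gene correlation
beyond the planted structure, batch effects, doublets, zero-inflation
beyond NB sampling, hexagonal spot geometry, ligand diffusion between
adjacent spots, or per-gene dispersion trends.  Passing the planted-truth
tests therefore demonstrates the pipeline's internal correctness and
calibration, not performance on real tissue.

## Numerical and degenerate-case conventions

Matrix Market files are 1-based on disk; ids are opaque case-sensitive
strings everywhere.  Genes that are constant after kernel smoothing get
zero correlations and are flagged (detected with a relative tolerance of
1e−10 since row-normalized weights leave rounding noise on a constant
gene).  Ortholog mapping is a plain two-column table: unmapped genes are
dropped (counted), many-to-one targets collapse by summing counts,
one-to-many sources keep the first listed target; the log-normalized layer
is invalidated by the collapse and must be recomputed.  Spearman rho on a
constant vector is NA and flagged, not coerced to 0.  All stochastic
steps — generation, pseudoreplicate partitioning, control-gene draws,
permutations, subsampling — take explicit integer seeds, and the pipeline
derives stage seeds from its master seed by fixed offsets, so a full run
writes byte-identical outputs on rerun (no timestamps are emitted).

## Problem sizes

The shipped validations run on desk-scale instances chosen to keep the full
suite in a few minutes on one CPU: presets with ~550–650 cells on 90–196
spots and 300–400 genes; DEG calibration at 2000 genes × 200–400 cells;
permutation calibration at 500 interactions × 200 cells × 1000
permutations × 10 seeds; assignment optimality against exhaustive
enumeration at ≤ 6 cells × 3 spots (50 instances); module recovery on 80
cells × 30 genes × 10 seeds.  All scale linearly or quadratically, so
larger instances are a matter of patience, not code change.

## Known limitations

The built-in mapper is a stand-in: it reproduces the *kind* of solution
(capacity-constrained, correlation-cost, globally optimal) of the
optimization-based mappers, not any specific tool's output.  Expression
matching systematically concentrates cell types into their best-matching
spots, so mapped colocalization is sparser than the underlying truth; rank
concordance survives this, absolute Jaccard values do not.  The pseudobulk
test is a simplified NB Wald (see above).  Only two-group DEG contrasts are
supported; enrichment analysis, embeddings, image handling and
HDF5-backed matrices are out of scope.
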