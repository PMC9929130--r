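---
title: "Models and methods behind metaniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modeling decisions in `metaniche`: the procedures
each stage implements, the parameters that matter and their defaults, what
the synthetic cohorts do and do not emulate, and the known limitations. The
package targets single-cell RNA-seq studies of metastatic tumor ecosystems,
where the analysis chain runs from raw counts to malignancy calls, clonal
structure, recurrent expression programs, cell–cell communication and
signature scores.

## Quality control and preprocessing

`qc_filter()` removes cells failing any of four rules: fewer than 200
detected genes; the top 2% of cells per sample by detected genes; the top 2%
per sample by total UMIs; or more than 50% mitochondrial content
(gene-symbol prefix `MT-` by default). The two top-fraction rules act as a
doublet surrogate in pipelines without an explicit doublet caller. Boundary
conventions are explicit and tested: a cell with exactly 200 genes or
exactly 50% mitochondrial content survives; with `k = floor(0.02 * n)` cells
to remove, the ceiling is the `(n − k)`-th order statistic and only cells
strictly above it are dropped, so ties at the ceiling survive. Ceilings are
computed per sample — pooled ranking would let a deeply sequenced sample
evict another sample's healthy cells — and the result carries its ceilings,
which can be passed back to re-apply the original thresholds; with fixed
ceilings the filter is idempotent.

`normalize_log()` scales each cell to 10,000 counts and applies
`log(1 + x)`. The target-sum/log1p dialect is fixed because downstream
thresholds ("expression > 0", "statistic > 0.1") are stated on this scale.
All-zero cells are left as zeros with a warning rather than dropped, since
QC is the place where cells are removed.

`cluster_cells()` runs exact PCA (an eigendecomposition of the gene–gene
covariance — deterministic, no randomized solver, so results are
reproducible and invariant to gene order), builds a shared-nearest-neighbor
graph with Jaccard edge weights (`k_neighbors = 20`), and applies Louvain
modularity optimization at `resolution = 1.2`, the resolution used for the
cohort this package emulates. `find_markers()` performs one-vs-rest Wilcoxon
rank-sum tests per gene (normal approximation with tie and continuity
correction, verified against `stats::wilcox.test`), keeps genes detected in
more than 10% of the cluster with natural-log fold change above 0.25, and
adjusts p-values by Benjamini–Hochberg within cluster. The fold change is
`log((mean(expm1(x_in)) + 1e-9) / (mean(expm1(x_out)) + 1e-9))`; the
pseudocount only guards empty clusters. `annotate_clusters()` assigns each
cluster the type whose marker list maximizes mean z-scaled expression; exact
ties go to the lexicographically first type and are flagged, and clusters
with no positive marker signal become `"unassigned"`.

## Expression-based copy-number inference

`infer_cnv()` implements the classic expression-window procedure: drop genes
detected in ≤ 20 cells; order the rest by chromosome and position; center
each gene on its cross-cell mean; clip at ±1.5 per-gene standard deviations
("ceiling" read as a symmetric bound); smooth per chromosome with a centered
101-gene running mean, truncating the window symmetrically at chromosome
ends (position *i* averages `[i−h, i+h]` with
`h = min(50, i−1, n−i)`, avoiding edge NAs); and subtract the mean profile
of the reference cells. Deviations are reported around 0 — "centered to 1"
in the field's descriptions is a display offset, not a different statistic.
Per-cell re-centering (subtracting each cell's median smoothed value) is
deliberately **not** applied: the contract is that a cell offset from the
reference by a constant *d* at every gene shows deviation exactly *d*,
which a re-centering step would destroy. The cost is a known artifact
discussed under limitations.

The CNV score is `log1p(mean(deviation²))` — zero for a neutral profile,
monotone in copy-number load, with the log taming heavy tails.
`call_malignant()` requires both the cell's score and its Ward-linkage CNV
cluster's mean score to exceed the 99th percentile of the reference scores;
the conjunction suppresses isolated noisy cells inside quiet clusters. The
quantile, clustering depth and event thresholds are exposed because no
standard fixes them; the defaults (`q = 0.99`, gain/loss thresholds ±0.15,
30-gene minimum span, 50% reciprocal-overlap event matching) were calibrated
on synthetic cohorts at the depth described below. An event carried by more
than 90% of a subclone's cells is canonical, below that noncanonical, with
carriage measured as the fraction of cells whose own mean deviation over the
span passes half the calling threshold. `build_clonality_tree()` places
events shared by all subclones on the trunk and nests subclones greedily by
shared remaining events; event sets violating perfect-phylogeny containment
attach at the deepest compatible node and are flagged as conflicts rather
than failing.

## Recurrent expression programs

`extract_modules()` subclusters each sample's malignant cells (the same
graph engine, or k-means on PC scores when `modules_per_sample` is fixed)
and takes each subcluster's top-100 genes by log fold change as a module
signature; a sample collapsing to one subcluster contributes its top-100
genes by mean expression. Module scores over all malignant cells use the
bin-matched control scheme of `module_score()`. `aggregate_modules()`
correlates module scores (Pearson), clusters `1 − r` with average linkage,
and cuts at `r = 0.3`; programs whose members span ≥ 2 samples are flagged
recurrent, and consensus genes are those in more than half the member
signatures (padded to 10 by membership frequency). Where the emulated
study's module count is known (~50), fixing `modules_per_sample` (e.g. 12
over 4 samples) reproduces that design and, by multiplying pure modules
relative to mixed-activity ones, keeps consensus signatures cleaner than
auto-resolution subclustering; both routes recover planted programs, and the
fixed-count route is what the acceptance checks exercise.

A cell is a program cell when it expresses (normalized value > 0) strictly
more than 70% of the program's consensus genes present in the matrix; the
program score of a sample is the exact count ratio. Dependency between
programs is the natural-log odds ratio of the joint program-cell 2×2 table
with the Haldane–Anscombe 0.5 correction in every cell — the published
thresholds ±0.1 only make sense on the log scale, since raw odds ratios are
nonnegative. The correction makes the statistic finite for degenerate
tables and exactly antisymmetric under complementing one indicator.

## Ligand–receptor permutation testing

`interaction_test()` scores each (pair, sender, receiver) combination by
the average of the ligand's mean expression in the sender type and the
receptor's mean in the receiver type (a `min` variant is available). The
null permutes type labels 1000 times;
`p = (1 + #{null ≥ observed}) / (n_perm + 1)` keeps p-values positive and
estimable. Significance requires statistic > 0.1 and p < 0.05. A
combination is only tested when the ligand is detected in more than 10% of
sender cells and the receptor in more than 10% of receiver cells — the
field's "thresholded across each cell type" step, given a concrete default.
Receptor complexes are out of scope; database rows are simple gene pairs.

## Signatures, cell cycle, entropy

`module_score()` subtracts, from the mean expression of a gene set, the
mean of control genes drawn per set gene from its expression-magnitude bin
(25 bins, 100 controls per gene, seeded) — a random set scores 0 in
expectation, and scores scale linearly with expression. `assign_phase()`
calls G1 when both S and G2M scores are ≤ 0 (noncycling), otherwise the
larger score's phase, with exact positive ties called S and flagged.
`expression_entropy()` computes profile Shannon entropy after removing
`RPL`/`RPS`/`ERCC` genes, with a gene-bootstrap standard deviation; it is a
deliberately simple stemness surrogate with closed-form anchors (uniform
profile over k genes → `ln k`; single gene → 0) rather than a reimplementation
of annotation-cluster-based entropy frameworks, whose internals are not
restated here. `dotplot_stats()` reports per cluster and gene the
expressing fraction and z-scaled mean, plus an explicit per-cluster ranking
so statements like "receptor A exceeds receptor B in this cluster" are
machine-checkable.

## The synthetic cohorts

`simulate_counts()` draws per-gene baselines from
`baseline_mean × lognormal(0, 1)`, multiplies per-cell lognormal library
factors (σ = 0.25), applies marker folds (default 8× on 20 genes per type,
spread along the genome so no smoothing window is dominated by one type's
markers), CNV segment folds in carrier cells, program activation folds in
active cells and ligand–receptor folds in sender/receiver types, then
samples negative-binomial counts (shared dispersion 2) with 5% independent
dropout. Defaults describe a cohort of 4 samples (alternating liver/brain),
~600 cells per sample across five types, and 2000 genes on 10 chromosomes.
`baseline_mean = 3` makes the expected cell depth ≈ 10,000 UMIs over the
2000-gene universe, matching the per-detected-gene depth of the 10x tumor
cohorts this generator emulates; at substantially lower depth the
log-normalized values discretize and window-smoothed CNV noise grows
unrealistically. Gene positions are evenly spaced indices — only order
matters to the 101-gene window. Program gene sets planted in tests are drawn
from genes with baseline means near 1 (baseline detection ~50–60%,
activated ~80–85%) because the fixed ">70% of genes expressed" rule is
uninformative for ubiquitously detected genes; this mirrors real tumor
programs, whose genes are induced rather than constitutive.

What the generator does **not** emulate: batch effects, ambient RNA,
doublets, UMI-level noise, gene–gene correlation beyond the planted
structure, and realistic chromosome lengths. Passing tests therefore show
that the implementations recover the planted structure under clean
negative-binomial noise, not that they are robust to every artifact of real
tissue data.

## Numerical choices and degenerate inputs

Seeds control every stochastic step (simulation, control-gene sampling,
community detection, permutations); identical inputs and seeds give
identical outputs. PCA is exact; hierarchical clustering and event calling
are deterministic. Degenerate inputs warn and proceed where a sensible
result exists (empty matrices, all-zero cells, unknown mitochondrial
prefixes, chromosomes shorter than the window, single-cell clusters,
degenerate reference scores) and error with the offending field named where
none does (unknown genes or types in a configuration, infeasible dependency
overlap, missing reference cells).

## Known limitations

- Library-size compensation couples loci: because each cell is normalized
  to a fixed total, a subclone with a large amplified fraction of its
  transcriptome is deflated genome-wide, which can surface as shallow
  spurious "losses" on unaffected chromosomes — and, since the profile
  contract forbids per-cell re-centering, these are visible in event lists
  as low-magnitude events and can be shared across subclones. Interpret
  genome-wide shallow losses accordingly.
- The >70% program-cell rule is sensitive to per-cell detection depth:
  cells with larger libraries detect more genes of *every* program, which
  biases the joint membership of independent programs toward apparent
  co-occurrence (on the order of +0.5 log-odds in simulation). The
  planted-activity route is unbiased; end-to-end, the ordering
  exclusive < independent < co-occurring is preserved.
- Mixed-activity subclusters (cells active in two programs) contribute
  signatures containing both programs' genes; when they dominate a module
  cluster the consensus absorbs partner genes. Fixed module counts per
  sample mitigate this; inspecting member modules of each program is
  recommended.
- The permutation test shares one permutation stream across all pairs
  (standard practice); p-values across pairs are therefore correlated, and
  calibration statements apply marginally.
- Problem sizes in the test suite (cohorts of a few hundred to a few
  thousand cells, 400–2000 genes) were chosen so the full suite and the
  acceptance script each run in minutes on one CPU; all statistics scale
  linearly or near-linearly in cells × genes except the SNN graph
  (quadratic in cells), which is comfortable to ~10⁴ cells.
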