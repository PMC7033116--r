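---
title: "Models and methods behind scmixtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmixtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the synthetic-data
generator, the numerical choices, and the open design decisions behind the
package. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute themselves.

## The study design being emulated

The package targets multi-sample droplet scRNA-seq studies of a genetic
tumor model: control and double-mutant mouse salivary glands, both sexes,
an early (P40) and a late (P90) stage, roughly a thousand UMIs and five
hundred detected genes per cell, and a tumor compartment consisting of
basal tumor cells, two rare cancer-stem-cell-like states (CSC1,
Wnt-high/basal-like; CSC2, luminal-primed) and luminal Clu+ cells arranged
along a single differentiation-like trajectory with continuous transitions.

## The synthetic-data generator

`simulate_dataset()` draws, for every cell, UMI counts gene-wise from a
negative binomial with mean `library_size x profile`, where the log profile
is

    baseline(g) + celltype_marker_offset + tumor_state_offset
      + program_loading(g) x program(t) + batch(sample)

* **Baseline**: per-gene log-normal weights with `baseline_sdlog = 1.4`.
  This value, together with the log-normal library size (median 1000,
  sdlog 0.35) and per-gene NB dispersion 0.3, reproduces the design's
  stated depth (median ~1000 UMIs and ~500 detected genes out of 2000
  genes); it was chosen by solving the expected-detection identity
  `E[detected] = sum_g 1 - (1 + mu_g / size)^(-size)` for the target.
* **Cell types**: acinar, duct, immune and basal populations with 30
  private marker genes each at a +2 natural-log offset. The optional sex
  effect shifts the duct proportion and mirrors the sexually dimorphic
  composition of the gland.
* **Tumor compartment**: a latent pseudotime `t in [0,1]` is drawn per
  tumor cell from a stage-dependent Beta distribution (`Beta(2,4)` at P40,
  `Beta(4,2)` at P90, so early-stage tumors sit earlier on the
  trajectory), and the population label follows fixed windows
  (basal tumor: 0–0.35, CSC1: 0.35–0.5, CSC2: 0.5–0.7, luminal: 0.7–1).
  Three expression programs drive the continuum: EMT, a falling sigmoid
  centered at 0.35; Wnt, a Gaussian bump at 0.45 (width 0.07); and a
  luminal program rising at 0.75. Each program spans 40 genes.
* **Program amplitudes** default to 2.5 (EMT, luminal) and 1.2 (Wnt), and
  the tumor states carry only mild private offsets
  (`tumor_marker_lfc = 1`, versus 2 for the discrete cell types). The
  asymmetry is deliberate: the terminal identity programs behave like
  on/off cohorts (the EMT signature is lost outright; Clu and Wfdc18 are
  specific to the luminal end), while the transient Wnt signature is a
  narrow cohort that is switched on mid-trajectory and inactivated again.
  A full-strength transient bump would make the Wnt-high state a geometric
  arch whose diffusion distance from the trajectory origin exceeds the
  states that follow it — a property of the bump geometry, not of the
  biology being emulated.
* **Genotype effect**: a log-odds shift (default +2) of tumor-lineage
  membership in double-mutant samples; `genotype_effect = 0` yields a null
  data set in which the genotypes are exchangeable. CSC-like states are
  rare by construction (their windows and the Beta laws put each at a few
  percent of cells); the real study reports them at under a percent, which
  the generator deliberately raises to keep them testable at desk scale.
* **What is not modeled**: ambient RNA, doublets, epitope (ADT) counts,
  and cell-cycle structure. Passing tests therefore certify the statistics
  under clean NB sampling with batch effects, not robustness to those
  artifacts.

`simulate_barcode_mixture()` models the pre-cell-calling barcode list:
log-normal real cells over an exponential ambient tail, with labels
returned for oracle use.

## Barcode knee selection

`knee_select()` locates the knee of the cumulative UMI fraction versus
log10 rank curve as its point of maximum concave curvature, computed by
second differences after interpolating long curves onto an even log-rank
grid and applying a five-point running mean. We first implemented the
maximum distance-to-chord rule on the same curve and found it fails
whenever the ambient tail carries a comparable share of total reads (its
extreme-distance point lands on the tail's broad shoulder rather than the
real-cell cliff); the curvature rule recovers a planted 500-cell knee to
within a few barcodes and degrades gracefully on degenerate inputs (no
concave bend selects everything). The rule is scale-invariant and has two
numerical knobs (grid size 512, smoothing window 5) that only matter for
curves longer than the grid.

## QC and normalization

Thresholds are read literally: at least 100 detected genes is inclusive,
less than 15% mitochondrial content and less than the optional gene
ceiling are strict. Cells are scaled to a common depth (1e4) and
log1p-transformed; optional covariate regression (UMI count,
mitochondrial/ribosomal fractions, as used for epitope-profiled runs)
replaces each gene by intercept-plus-residuals from a per-gene linear
model, and a constant covariate is a no-op by construction.

## Feature selection, PCA, clustering, embedding

Highly variable genes are ranked by dispersion (variance over mean of
depth-normalized expression) standardized within 20 mean-expression bins;
each bin's spread is floored at 1% of the global spread so a near-constant
bin cannot promote its members' noise. Significant PCs follow a
jackstraw-style scheme: permuting 1% of each gene's values gives a null
spectrum that preserves almost all structure; a prefix count of components
whose observed eigenvalue exceeds the null's 95th percentile is returned.
Clustering is shared-nearest-neighbor Jaccard weights with modularity
community detection at a caller-chosen resolution. The 2D embedding
contract only requires a deterministic, neighbor-preserving map whose
coordinates downstream code treats as opaque; the implementation projects
onto the two leading principal axes, which satisfies every stated property
(determinism, blob separation, coincident duplicates) without a stochastic
optimizer.

## The mixing statistic

`D_j = sum_i q_i log(q_i / q_i0)` with natural logs, `0 log 0 := 0`, and
`q0` estimated from all cells (groups absent from the data are dropped, so
`q0 > 0` always). Neighborhoods are the 30 nearest neighbors in PCA space
with self excluded and ties broken by cell index. Two exact properties
anchor the tests: `0 <= D_j <= max_i log(1/q_i0)`, and the chain rule over
nested groupings (replicates inside biological factors), which
`decompose_mixing()` implements term by term so additivity holds to
machine precision. Under i.i.d. labels the mean divergence approaches
`(|I|-1)/(2k)` (the chi-square approximation of the KL divergence of
multinomial proportions), which the suite verifies against the permutation
null within Monte-Carlo error. The summary "fraction of structure
explained by biology" is `mean(D_between)/mean(D_total)`; it is our
operationalization of variance-explained for this statistic — exact,
additive and base-invariant — and no claim is made that it reproduces any
particular figure on real data.

## Density contrasts and refinement filters

Group densities on the embedding are Gaussian product-kernel estimates
with an isotropic Scott bandwidth per group (root mean per-axis variance
times n^(-1/6)); isotropy makes the contrast exactly invariant under
rotations and translations of the embedding. The contrast is
`log2((f_A + eps)/(f_B + eps))` with `eps` defaulting to 1e-3 of the
maximum estimated density, keeping values finite where one group vanishes
while preserving exact antisymmetry under group swap. The two refinement
filters follow their stated rules: distance beyond `n_sd = 3` SDs of a
cluster's center distances (coincident clusters have SD 0 and keep
everything; singletons are kept with a warning), and a strict-majority
vote (> k/2 for one single other label) among the k = 10 nearest
embedding neighbors. The majority filter is deliberately not idempotent —
a second pass would vote on a changed neighbor base — and is applied once.

## Pseudobulk differential expression

Counts are pooled exactly per (sample, group); columns with no cells are
dropped; size factors are median-of-ratios with a logged total-count
fallback when no gene is everywhere nonzero. Genes must be detected in at
least 5% of the relevant cells (inclusive). Each gene is fit by an NB
log-linear model with log size factors as offset and centered log10 cell
count as covariate (centering decouples the intercept; log10 keeps the
scale stable). Dispersion is per-gene maximum likelihood with a
method-of-moments fallback and no shrinkage across genes. Plain Wald z and
chi-square LRT references proved strongly anticonservative at twelve
columns, so both tests are quasi-likelihood corrected: standard errors are
inflated by the root Pearson overdispersion (floored at 1) and referred to
t, and the LRT deviance difference becomes an F statistic on
(groups - 1, residual) degrees of freedom. This is the standard remedy in
replicate-level count testing and is what the calibration suite certifies
(type-I within [0.03, 0.07], uniform LRT null, power above 0.8 for 2-fold
changes at dispersion 0.05 and pooled means around 500).

## Composition testing

Cluster membership per sample is binomial with logit link; the sample is
the unit of extra-binomial variation. The default fit integrates the
per-sample random intercept out marginally as a beta-binomial and
maximizes that likelihood directly (BFGS with an analytic-free Hessian),
with Wald t statistics on (samples - parameters) degrees of freedom. The
Laplace-approximate logit-normal fit (lme4) is available as a backend but
is not the default: with a few dozen samples it underestimates the
between-sample variance and its Wald z p-values run anticonservative,
which the calibration suite would reject. Quasi-complete separation (a
cluster present in essentially one sample) is flagged and the affected
p-value set to NA.

## Gene-set enrichment and module scores

Enrichment on per-gene log2 fold changes is an unequal-variance two-sample
t test of member versus non-member genes (two-sided; direction read off
the member mean), BH-adjusted across sets; sets with fewer than three
expressed members are skipped. The reporting filter keeps sets with
q < 0.1 and |mean log2 FC| strictly above 0.5, and ignores sets with
strictly more than 10% ribosomal members. Module scores subtract, from the
mean expression of the set genes, the mean of `n_ctrl = 100` control genes
drawn per set gene from the same average-expression bin (25 bins, with
replacement when bins are small); never-expressed genes are excluded from
binning and the control pool so padding the matrix with silent genes
cannot change a score. Scores may be computed on neighbor-smoothed
expression (`neighbor_smooth()`, a plain k-NN mean); smoothing is off by
default everywhere.

## Diffusion map and pseudotime

The kernel is Gaussian with self-tuning local scales (the distance to the
`k_kernel = 15`th neighbor), truncated to the symmetric k-NN support, with
anisotropic density normalization at `alpha = 1` and a final symmetric
conjugation to obtain a real spectrum. Truncation matters: a dense kernel
on high-dimensional expression data mixes in one step, its nontrivial
eigenvalues collapse toward zero, and the spectral weights
`lambda/(1-lambda)` then barely distinguish signal from noise components;
the k-NN-supported walk mixes slowly, pushing the leading eigenvalues
toward 1 and restoring the intended weighting. Distances default to
cosine (cells scaled to unit norm), which is robust to residual depth
differences; Euclidean is available. A disconnected support graph is an
error reporting component sizes rather than a silent per-component
embedding.

Pseudotime is the diffusion distance to the root over components whose
weight exceeds 1% of the leading weight, min-max scaled to [0, 1]. Given a
root cluster, the root cell is that cluster's extreme cell on DC1, with
the extreme chosen so the root cluster attains the lowest median
pseudotime — the biology-anchored orientation (the origin population
starts the trajectory), with the caveat that trajectory directionality is
a modeling choice, not an observed quantity. Trajectory curves and program
profiles are first-degree LOESS fits over pseudotime (span 0.5 by
default, tricube weights, direct surface) with pointwise 95% bands from
the local standard errors. The per-sample reproducibility check re-embeds
each sample with more than 10 cells (strict) and reports |Spearman rho|
against the global pseudotime; the stage-shift test is OLS of pseudotime
on the stage indicator over double-mutant samples with at least 5 cells
(inclusive), with CR0 cluster-robust standard errors and a t reference on
(samples - 1) degrees of freedom — the cell-level-with-clustering choice
is ours, as the granularity of the original analysis is not recoverable
from its description.

## Pipeline driver and determinism

`run_pipeline()` executes the stages in their canonical order, derives a
substream seed per stage from the master seed and the stage name, writes
one TSV per stage plus a structured log line (stage, parameters, sizes),
and dumps the fully resolved configuration next to the outputs. Reruns of
the same configuration are byte-identical in every stage output. The
command-line surface of the package is this function plus
`scripts/acceptance.R`; no separate shell tool is shipped.

## Problem sizes used by the test suite

The suite exercises the generator at 26 x 100 cells for design checks,
12 x 67-cell tumor-only simulations (~800 cells, matching the scale at
which the trajectory analyses are specified) for recovery, 2000-gene /
twelve-column fixtures for DE calibration, and 500-replicate nulls for the
composition and stage-shift tests. These sizes keep the full suite within
a few minutes on one core while leaving the Monte-Carlo error of each
calibration check well inside its acceptance band.

## Known limitations

* The generator's clean NB world omits ambient RNA, doublets and
  cell-cycle effects; calibration under those artifacts is untested.
* The trajectory machinery assumes a single path; branching detection is
  out of scope.
* The jackstraw-style PC count uses a prefix rule and a fixed 1%
  permutation fraction; deeply nested weak signals below the first
  non-significant component are not counted.
* Neighbor-average smoothing is a crude stand-in for model-based
  imputation and is disabled by default.
* The beta-binomial composition default trades the exact logit-normal
  random-effect geometry for calibrated marginal inference; variance
  components are not separately reported.
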