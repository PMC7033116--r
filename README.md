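# scmixtraj

Sample-mixing entropy QC, pseudobulk differential expression and diffusion
trajectories for multi-sample droplet single-cell RNA-seq.

## The problem

Multi-sample droplet scRNA-seq studies of tumorigenesis — dozens of
biological replicates spanning genotypes, sexes and disease stages — pose a
chain of analysis questions that generic toolkits answer only partially:

* Are the samples well mixed in expression space, and is the residual
  structure explained by the biology (genotype, sex, stage) or by technical
  replicate effects?
* Where on the embedding do two sample groups differ in abundance, and
  which cells are embedding artifacts?
* Which genes and cell-type proportions differ between genotypes, tested at
  the replicate level where count models are valid?
* Along which transcriptional path does the tumor compartment develop, and
  does that path shift between an early and a late stage?

`scmixtraj` packages these steps as composable functions with a synthetic
data generator that emulates the study design end to end (26 samples, 12
control and 14 double-mutant, a median of roughly 1000 UMIs and 500 detected
genes per cell, and a four-population tumor trajectory), so every statistic
ships with parameter-recovery tests against known ground truth.

## The core statistics

**Neighborhood mixing divergence.** For cell *j* with the k = 30 nearest
neighbors N(j) in PCA space, the statistic is the Kullback–Leibler
divergence (natural log)

    D_j = sum_i q_i * log(q_i / q_i0)

where `q_i` is the proportion of neighbors from sample group *i* and `q_i0`
the group's proportion in the whole data set. `D_j = 0` means the
neighborhood mirrors the global composition. Permutation controls
(`shuffle_null`) and an exact chain-rule decomposition
(`decompose_mixing`) split each cell's divergence into a biological-factor
component and a within-factor replicate component:
`D_total = D_between + sum_b q_b D_within,b`, summarized by
`mean(D_between) / mean(D_total)`.

**Pseudobulk NB tests.** Counts are pooled per (sample, group), normalized
by median-of-ratios size factors, and tested per gene with a
negative-binomial log-linear model carrying centered log10 cell count as a
covariate. Inference is quasi-likelihood corrected (Pearson-overdispersion
scaling, t/F references on residual degrees of freedom), which keeps type-I
error at its nominal level at replicate-level sample sizes.

**Diffusion trajectory.** A Gaussian kernel with per-cell local scales,
truncated to the k-NN support and density-normalized, yields a stochastic
operator whose nontrivial eigenvectors are the diffusion map. Pseudotime is
the diffusion distance to a root cell chosen from the origin population,
and LOESS smoothing draws the trajectory curve and program profiles (EMT,
Wnt, stemness) over pseudotime; a cluster-robust linear model tests the
early/late stage shift.

## Worked example

```r
library(scmixtraj)

cfg <- sim_config(n_samples_control = 4, n_samples_mutant = 6,
                  cells_per_sample = 80, seed = 42)
d   <- simulate_dataset(cfg)

qc     <- qc_filter(d$counts, d$genes$mito)        # >=100 genes, <15% mito
counts <- d$counts[, qc$keep]
meta   <- d$metadata[qc$keep, ]
truth  <- d$truth[qc$keep, ]

expr <- normalize_log(counts)
hvg  <- select_hvg(expr, 500)
pca  <- pca_embed(expr[hvg, ], n_pcs = 10)

## how well do the 10 samples mix in expression space?
nn <- knn_graph(pca$scores, k = 30)
mixing_divergence(nn, meta$sample)
#> Neighborhood mixing divergence (KL, nats)
#>   cells: 800   k: 30   groups: 10
#>   mean D: 0.2247   upper bound: 2.303

fm  <- setNames(paste(d$samples$genotype, d$samples$sex, d$samples$stage,
                      sep = "_"), d$samples$sample)
dec <- decompose_mixing(nn, meta$sample, fm)
round(dec$fraction_between, 3)
#> [1] 0.491

## trajectory of the tumor compartment
tum <- which(!is.na(truth$population))
dm  <- diffusion_map(expr[hvg, tum], n_comps = 10, k_kernel = 15)
dpt <- diffusion_pseudotime(dm, root_cluster = "basal_tumor",
                            labels = truth$population[tum])
cor(dpt$pseudotime, truth$t[tum], method = "spearman")
#> [1] 0.836
round(tapply(dpt$pseudotime, truth$population[tum], median), 2)
#> basal_tumor  CSC1  CSC2  luminal_Clu
#>        0.34  0.84  0.89         0.93

stage_shift_test(dpt$pseudotime, meta[tum, ])
#> Stage shift in pseudotime (P90 - P40)
#>   slope: 0.304  p: 6.96e-05  ( 122 cells, 6 samples )
```

The mean divergence of 0.22 nats (against an upper bound of 2.3) says the
samples mix well; about half of the residual neighborhood structure is
attributable to genotype/sex/stage rather than replicate identity. The
recovered pseudotime rank-correlates at 0.84 with the generator's latent
trajectory position, orders the four tumor populations correctly
(basal tumor < CSC1 < CSC2 < luminal Clu+), and places P90 cells later
than P40 cells (positive slope, p < 1e-4).

A full driver, `run_pipeline(pipeline_config(...))`, chains all stages
(knee selection, QC, normalization, HVG/PCA, clustering, 2D embedding,
mixing QC, density contrast, refinement filters, composition tests,
pseudobulk DE, trajectory) deterministically from one master seed and
writes one TSV per stage.

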