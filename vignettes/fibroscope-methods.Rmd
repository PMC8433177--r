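---
title: "Methods: staging liver fibrosis from bulk transcriptomes and tile morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging liver fibrosis from bulk transcriptomes and tile morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroscope)
```

# Scope

`fibroscope` implements a pipeline for characterizing liver fibrosis in
NAFLD/NASH cohorts along four axes:

1. a continuous per-sample fibrosis score (**ImageScore**) learned from
   tile-level morphometric features of histology images;
2. **cell-type deconvolution** of bulk liver RNA-seq against a multi-subject
   single-cell reference, with a pseudo-bulk benchmark;
3. **cell-type-specific differential expression** between advanced fibrosis
   (F3/F4) and non-fibrotic (F0/normal) samples by proportion-interaction
   regression;
4. **gene signatures** of fibrosis severity derived from per-gene
   proportional-odds models, a composite sample score, and lasso selection.

A first-class synthetic-data module generates cohorts with the statistical
structure these analyses assume, so that every stage can be exercised and
calibrated without any external download. Fibrosis stage is the ordered
factor `N < F0 < F1 < F2 < F3 < F4` (normal histology, then the NASH CRN
scale 0 = absent to 4 = cirrhosis).

# The synthetic cohort generator

`study_config()` fixes the study conditions; `generate_study()` draws a full
cohort. The defaults mirror a 143-biopsy cohort heavily used in this kind of
work: per-stage sample counts N=31, F0=35, F1=30, F2=27, F3=8, F4=12; four
major liver cell types (hepatocytes, cholangiocytes, hepatic stellate cells,
macrophages); biopsy images with 8 to 500 tiles each.

**Latent severity.** Each sample carries a hidden continuous severity equal
to its stage's numeric target (N=-1, F0..F4 = 0..4) plus N(0, 0.15) jitter.
This creates the within-stage continuum that the ImageScore is meant to
expose; the jitter sd of 0.15 keeps adjacent stages essentially
non-overlapping (their targets are 1 apart) while still ordering samples
within a stage.

**Single-cell reference.** Per cell type, archetype gene means are lognormal
(sdlog 1) with a small cross-type jitter (sdlog 0.2). Each type carries
`markers_per_type` planted markers whose own-type archetype mean is 64 times
the other types'; the contrast is deliberately far above the advertised
10-fold floor because observed per-type count means are compressed by
cell-type library-size differences (hepatocytes are generated with twice the
library size of the other types, reflecting their larger transcriptome) and
by subject-level lognormal jitter (sdlog 0.3). Cells are negative-binomial
(variance mu + phi mu^2) around each subject's relative profile.

**Proportions.** Each sample's cell-type fractions are a Dirichlet draw
around its stage's mean vector. The stage means move hepatocytes from 0.82
(normal) down to 0.32 (cirrhosis) while cholangiocytes (0.02 to 0.18), HSCs
(0.06 to 0.24) and macrophages (0.10 to 0.26) rise — the qualitative picture
reported by deconvolution of real NASH cohorts, with the cholangiocyte and
macrophage expansion strongest in advanced disease. The concentration
parameter defaults to 50, i.e. a within-stage sd of roughly 0.05-0.08 for
the major types. This was chosen to match the substantial
patient-to-patient spread such studies show; it is a consequential choice:
much tighter proportions would make stage trends trivially clean but would
also starve the proportion-interaction regression (below) of the
within-group variation it needs to identify cell-type-specific effects.

**Bulk mixtures.** The expected expression of gene g in sample i is

$$\mu_{gi} = L_i \sum_c p_{ic}\,\theta_{gc(s_i)}\,2^{\beta_{gc} d_i}\; \cdot\; 2^{\mathrm{lfc}_g \cdot \mathrm{sev}_i}$$

with `L_i` a lognormal library size (sdlog 0.3), `theta` the subject-specific
relative profile of the reference subject assigned to the sample, `d_i` the
advanced-fibrosis indicator (stage F3/F4), planted stage-monotone effects
`lfc_g` on a `de_frac` fraction of genes, and planted cell-type-specific
disease effects `beta_gc` (magnitude `celltype_lfc_scale`, one random type
per affected gene). Counts are negative-binomial with dispersion 0.1 by
default; `exact = TRUE` returns the expectations themselves, which the test
suite uses as a closed-form oracle. All planted effects are recorded in
`$truth`.

**Tiles.** Each of the eight morphometric features (tissue/void compactness,
void count, equivalence radius, and four collagen/void area measures) is an
affine function of latent severity plus N(0, `tile_noise_sd`) noise.
Collagen-area features load positively, compactness features negatively,
mirroring the observation that fibrosis-associated tile clusters are driven
by collagen abundance and voids. With `tile_noise_sd = 0` the generator is
exactly deterministic given the metadata, another closed-form oracle.

**What the generator does not emulate:** gene-gene correlation beyond what
mixing induces, batch effects on expression, zero-inflation beyond the NB,
cross-species reference integration, and real marker-gene identity. Passing
tests therefore demonstrate internal correctness and statistical behavior
under the stated model, not performance on any real cohort.

# ImageScore

One repetition down-samples every image to six tiles (images with fewer keep
all; the selection is canonicalized by tile id so results are invariant to
input row order), then runs patient-level cross-validation (20 folds by
default): per fold, a PCA basis (centered, unit-scaled, smallest component
count reaching 90% cumulative variance) is fit on training tiles only; each
patient is summarized as the componentwise median of its tiles' PC scores;
an epsilon-insensitive RBF support-vector regression (C = 1, epsilon = 0.1,
gamma = 1/k over k components) maps training patient features to the numeric
stage targets N=-1, F0..F4=0..4; held-out patients are predicted from their
own projected tile medians. After `n_reps` repetitions (100 by default) the
per-sample ImageScore is the median of its repetition predictions — an
aggregation that bounds the influence of any minority of aberrant
repetitions by the size of their perturbation.

Design notes. Cross-validation splits patients, not tiles: splitting tiles
would place tiles of one patient on both sides of a fold and leak identity.
The stage targets make the mapping affine in stage order with normal
histology preceding F0. The SVR and PCA hyperparameters are the conventional
defaults of the underlying implementations and are exposed in
`imagescore_config()`.

**Reporting ranks against a tied ordinal.** Kendall tau-b (what `cor()`
computes) is reported for score-vs-stage agreement. With 143 samples over 6
stages, a continuous score cannot reach tau-b = 1: the stage tie structure
caps it at `sqrt((n0 - T)/n0)` (about 0.90 for the default cohort) no matter
how good the ranking. `compute_imagescore()` therefore also reports
Goodman-Kruskal gamma, which is 1 exactly when every stage-untied pair is
ordered correctly; the noiseless generator achieves gamma = 1.

`cluster_tiles()` k-means the standardized PC scores of all tiles into four
groups (10 restarts) and reports each sample's cluster-occupancy ratios and
their rank correlation with stage; on default synthetic cohorts the
collagen-heavy cluster's ratio rises with stage.

# Deconvolution

`build_design()` summarizes a labeled reference into per-subject relative
profiles (each cell type and subject's mean expression scaled to sum to 1),
their cross-subject mean and variance, and per-type cell-size factors (mean
cell library size). `deconvolve()` then iterates, per bulk sample,

1. a weighted non-negative least-squares solve for raw loadings q
   (Lawson-Hanson NNLS on the weight-scaled system), and
2. the gene-weight update `w_g = 1/(nu + sum_c q_c^2 v_gc)`, `nu = 1e-8`,

until the relative change of q drops below 1e-6 (100 iterations cap;
non-convergence is reported, not thrown). Genes whose profiles disagree
across reference subjects are thus progressively down-weighted — the
cross-subject-consistency principle of MuSiC-style deconvolution; the
specific iteration here is this package's own and is not a clone of that
implementation. Both bulk and reference are reduced to relative abundance
before solving, separating composition from transcript volume; loadings are
converted to cell fractions by `p_c = (q_c/S_c)/sum(q/S)`. No marker
pre-selection is applied: the gene set is simply the bulk/reference
intersection minus all-zero reference genes.

The pseudo-bulk benchmark (`make_pseudobulk()`) draws target proportions
from a flat Dirichlet, samples that many cells per type without replacement
from one reference subject, sums their counts, and records realized
cell-count fractions as truth, so `evaluate_recovery()` measures the
estimator against an exact standard. Scale invariance, exact identifiability
of noiseless mixtures, and the reduction to plain NNLS under zero
cross-subject variance are all enforced by tests.

`associate_proportions()` reports per-type correlations with stage and with
the ImageScore, per-stage means and sds, and flags cell types predicted
below 5% at every stage — such estimates are dominated by model uncertainty
and are excluded from interpretation.

# Cell-type-specific differential expression

With disease = {F3, F4} and control = {F0, N}, `ctassoc()` fits per gene the
no-intercept linear model

$$y_i = \sum_c p_{ic}\alpha_c + \sum_c p_{ic} d_i \beta_c + \gamma^\top z_i + \varepsilon_i$$

on `y = log2(TPM + 1)`, so the interaction coefficient beta_c reads directly
as the cell-type-specific disease log2 fold change. Sex is adjusted for by
default. Because proportions sum to 1 the design is near-collinear; a ridge
stabilizer (1e-6) on the interaction block keeps the normal equations
well-posed while leaving well-conditioned estimates numerically equal to
OLS (enforced by test). Wald t statistics use the sandwich variance of the
ridge-stabilized solve; Benjamini-Hochberg correction is applied jointly
across all gene-by-type tests.

Two calibration points shape the test suite. The *null* for false-positive
calibration uses stage-independent proportions: when proportions are
stage-linked, the mild nonlinearity of log-transformed mixtures is
correlated with the disease indicator, and the check would measure model
misspecification rather than test calibration. The *power* check plants
|log2FC| = 1 effects and scores sign recovery only in cell types with mean
proportion at least 0.3: the standard error of an interaction coefficient
scales inversely with the within-group spread of that type's proportion, so
rare types are intrinsically poorly identified (the same reason the <5%
flag exists downstream).

`select_markers()` calls a gene a marker of type c when its pooled mean
expression (counts per 10k) is at least 1 and at least 4-fold every other
type's; with fold > 1 the sets are disjoint by construction.
`overlap_with_clusters()` counts marker intersections with expression-
pattern clusters.

# Gene signatures

The variance-stabilizing transform stand-in is `log2(CPM + 1)`: the
downstream procedure only requires a deterministic monotone transform with
roughly stabilized variance, and a user-supplied externally transformed
matrix can be passed instead.

**Per-gene ordinal models.** `fit_ordinal_per_gene()` fits the proportional
odds model `P(Y <= k | x) = logistic(zeta_k - beta x)` per gene by
Newton-Raphson with analytic gradient and Hessian, step halving, and a
gradient tolerance of 1e-8, starting from the zero-slope solution (empirical
cumulative logits). A native fitter is used because thousands of models are
fit per run and formula-based fitters spend most of their time in model-
frame construction; the test suite pins the fitter against `MASS::polr` (to
1e-6), against `glm()` in the two-level reduction, and against the
closed-form thresholds for balanced zero-slope data. Constant genes and
quasi-separated genes (|beta| escaping past 50) are flagged non-converged
and excluded downstream; non-coding genes receive no special handling.

**Gene scores and the composite.** The gene-level score of sample s is the
model-expected stage level, `sum_k k P(Y = k | x_gs)` with levels coded
0..K-1 — the natural probability-weighted reading of a "weighted gene-level
score" under an ordinal fit. Genes are ranked by the coefficient of
variation of their scores (sd over |mean|; genes with |mean| < 1e-8 are
excluded, ties broken lexicographically for determinism), and the composite
sample score is the mean over the top 1000 genes. A gene whose expression is
unrelated to stage yields near-constant scores and ranks last; planted
monotone genes dominate the top of the ranking regardless of their direction
(the ordinal model orients each gene), which is why the composite rises with
stage even when half the planted effects are down-regulations.

**Lasso.** `fit_lasso_signature()` standardizes predictors and computes the
lasso path (100 log-spaced penalties spanning 4 decades below the all-zero
lambda) with k-fold cross-validated MSE, via the standard coordinate-descent
implementation. Lambda selection rules: `min_mse`, `one_se`, or
`target_size:k` (the smallest-CV-MSE lambda whose path solution has exactly
k nonzero genes; nearest size with a warning when the grid has no exact
match — signature sizes are data-dependent). `validate_lambda()` recomputes
the CV MSE at a fixed lambda under a fresh fold split (e.g. five folds to
confirm a ten-fold choice). `score_and_validate()` applies a signature to
any expression matrix using the stored centers and scales, treating missing
signature genes as zero (with a warning; fewer than half present is an
error), and reports rank agreement with stage and with the composite.

**Stage coding.** All six levels, normal included, enter the ordinal fits
coded 0..5, consistent with the ImageScore target order; a restricted level
subset can be analyzed by subsetting the metadata. Whether normal histology
should enter as its own ordinal level is genuinely open; including it uses
all samples and matches the rest of the package's stage scale.

**Trend clustering and set arithmetic.** `cluster_gene_patterns()` z-scores
each gene, summarizes it as its per-stage mean trajectory, clusters
trajectories by average-linkage hierarchical clustering on correlation
distance, and reports only clusters with strictly more than 50 genes.
`gene_set_overlap()` performs case-normalized intersection/union arithmetic;
the packaged 26- and 98-gene signature lists (and a published 25-gene
external signature with its cluster assignment) ship as plain-text fixtures
for exactly this arithmetic — the package makes no claim of re-deriving
their identities, which would require the original cohort's raw data.

# Numerical choices and degenerate inputs

- NNLS weights are relative, so the stabilizer `nu = 1e-8` only matters for
  genes with near-zero cross-subject variance; uniform weights reduce the
  estimator to single-pass NNLS.
- All-zero bulk samples, empty tile tables, zero-total count columns,
  duplicate identifiers and mismatched sidecars are rejected with messages
  naming the offending object.
- PCA scaling treats zero-variance features as scale 1; a fully constant
  tile table yields constant (fold-level) SVR predictions rather than an
  error.
- Dirichlet draws with concentration tending to infinity collapse to the
  stage means; NB dispersion tending to 0 approaches the Poisson and the
  `exact` mode bypasses sampling entirely.
- Every generator and every stochastic stage takes an explicit seed;
  `run_all()` derives per-stage seeds deterministically from one global seed
  and records them, with output checksums, in its manifest.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
the default cohort shape (143 samples): a 2000-gene reference with 250 cells
per subject and type for the deconvolution benchmarks (50 pseudo-bulks of
400 cells), 2000-gene cohorts at n = 80 in the disease/control groups for
DE calibration and power, a 5000-gene cohort with 200 planted monotone genes
for the composite-score recovery, and 25 down-sampling repetitions for the
ImageScore runs. These sizes were chosen so the whole suite completes in a
few minutes while keeping every estimate comfortably away from
small-sample artifacts.

# Known limitations

- The deconvolution weight iteration follows the cross-subject-consistency
  principle but is not algebraically identical to any published
  implementation; absolute proportion estimates on mixtures with planted
  expression effects show the expected compositional bias even when stage
  trends are recovered perfectly.
- The proportion-interaction model estimates cell-type effects only up to
  the linear approximation of log-mixture expression; rare cell types are
  weakly identified by design, which the <5% flag makes explicit.
- The 26/98-gene fixture lists are inputs for set arithmetic, not recovery
  targets.
- ImageScore consumes tile feature tables; image processing itself (tiling,
  collagen segmentation) is out of scope.
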