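---
title: "Multiscale feature extraction and fusion for aMCI classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale feature extraction and fusion for aMCI classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcifuse)
```

## The problem

Amnesic mild cognitive impairment (aMCI) is a memory-dominant prodromal stage
of Alzheimer's disease. Resting-state fMRI offers non-invasive markers of the
condition, but cohorts are small (tens of subjects) while the data are
high-dimensional (thousands of voxels, 4,005 region-pair connections), so the
central statistical problem is selecting a handful of discriminative features
without drowning in noise. `mcifuse` implements a complete, testable pipeline
for this problem: per-subject representations (ReHo, ALFF, functional
connectivity), two feature-selection algorithms operating at different scales,
feature fusion, and leave-one-out cross-validated (LOOCV) classification.

Because the clinical data this design targets are access-restricted, the
package ships a synthetic cohort generator with *planted, known* effects.
Every downstream claim the test suite makes is checked against that planted
ground truth or against an independent oracle computation.

## Per-subject representations

Each subject arrives as a preprocessed 4-D volume (default emulated design:
140 time points at TR = 3 s, the first 5 discarded). Three representations
are computed:

* **ReHo** (regional homogeneity): Kendall's coefficient of concordance `W`
  of each voxel's band-passed time course with its 26 neighbours,
  `W = 12 * sum_t (R_t - K(T+1)/2)^2 / (K^2 (T^3 - T))`, where `R_t` is the
  rank sum at time `t` over the `K` series. `W` is 1 for perfectly concordant
  neighbourhoods and has expectation `1/K` for independent noise.
  Neighbourhoods are clipped to the brain mask, so boundary voxels use only
  in-mask neighbours rather than erroring.
* **ALFF** (amplitude of low-frequency fluctuation): the mean Fourier
  amplitude (`2|X_k|/T`) over 0.01–0.08 Hz of the linearly detrended series.
  No mALFF-style standardization is applied by default.
* **Connectivity**: signed Pearson correlation of the 90 regional mean time
  series (AAL-90 convention). The absolute value is taken only later, when
  the network graph is built, because edge-level feature selection benefits
  from the sign.

The band-pass filter is a zero-phase hard FFT mask after linear detrending,
with DC always excluded. This choice is exactly testable on pure tones
(in-band amplitude preserved within 5%, out-of-band attenuated by more than
90%) and matches the behaviour of the standard resting-state toolchains
closely enough for the statistics downstream.

## MGS-WBC: volatility detection plus dual significance masks

Feature selection for maps and edges uses two criteria together:

1. **Within-class volatility**. For each feature location and group, the
   variable coefficient `VC = sd_pop / mean * 100` (population divisor `n`) is
   computed; locations whose VC falls in the lowest 5% of each group are
   "stable". VC is undefined when the group mean is numerically zero
   (|mean| < 1e-8) and such locations never enter the ranking; ReHo and ALFF
   are positive, so the guard matters only for edge features. The two groups'
   keep-sets are combined by **intersection** by default: the design intent is
   that a feature is trusted only when it is stable *within both classes*,
   and reports quote both groups' VC values. A union rule is available behind
   a flag for sensitivity analyses.
2. **Between-class difference**. A pooled-variance two-sample Student t-test
   (sign convention: aMCI minus HC, so decreases in patients give negative t)
   yields a p-value per location. Two masks are built: the *strict* mask
   `p < 0.001` (the traditional single-threshold selection) and the *band*
   mask `0.001 < p < 0.05` intersected with the volatility mask. The two are
   disjoint by construction; their union is the final selection.

In voxel space, each mask is reduced to connected components (26-connectivity,
the resting-state convention) and components smaller than 5 voxels are
dropped. Each surviving cluster contributes **one feature per subject: the
mean of the subject's map over the cluster**. Cluster means rather than raw
voxels keep the dimensionality equal to the number of significant regions,
which is how the design's region counts (e.g. ten regions for ReHo) are
reported; voxelwise extraction would inflate the feature count by one to two
orders of magnitude at these sample sizes. In edge space no clustering is
applied and each selected edge contributes the subject's signed correlation.

Uncorrected thresholds are deliberate: the method is defined with fixed
uncorrected cut-offs, and adding FDR/FWE correction would change the method
being tested. Feature selection is computed once on the full cohort,
reproducing the upstream design; note that this is optimistic relative to
selection nested inside every CV fold, which is why the synthetic acceptance
checks rely on planted effects rather than on absolute accuracy values
carrying meaning for real data.

## VGBN-LM: a global network feature from the graph Laplacian

Edge-level features are local. To capture global network organization, each
subject's network is summarized by one 90-vector:

1. Build the graph with weights `w_ij = |r_ij|` and zero diagonal — the full
   weighted graph, with no Gaussian-kernel weighting and no k-nearest
   neighbour sparsification.
2. Form the degree matrix `D_ii = sum_j w_ij` and Laplacian `L = D - W`, and
   solve the generalized eigenproblem `L y = lambda D y`. The implementation
   diagonalizes the symmetric normalized Laplacian `D^{-1/2} L D^{-1/2}`, so
   all eigenvalues lie in [0, 2], every eigenvector satisfies `y' D y = 1`,
   and residuals `||L y - lambda D y||` are checked against a 1e-8 bound.
3. Select the optimal vector. The underlying constrained minimization of
   `y' L y` subject to fixed `y' D y` splits into a `lambda != 1` branch with
   objective `lambda y' W y / (1 - lambda)` and a `lambda = 1` branch
   (solutions of `W y = 0`). The printed form of the second branch's
   objective (`y' D y`) is inconsistent with the objective being minimized
   (`y' L y`); this implementation evaluates `y' L y` for **both** branches,
   which is the internally consistent reading. Under the `y' D y = 1`
   normalization every candidate's objective equals its eigenvalue, so the
   minimizer — after excluding the trivial pair (`lambda ~ 0`, constant
   vector, degenerate objective 0) — is simply the smallest non-trivial
   generalized eigenvalue's eigenvector, a Fiedler-type vector of `(L, D)`.
   The `sigma` constant of the constraint is defined only through the optimal
   solution itself; fixing `y' D y = 1` resolves that circularity and makes
   `sigma` the post-hoc value of the chosen solution. Ties (degenerate
   Fiedler values, e.g. complete uniform graphs) are broken by the smallest
   eigenvalue index, which is deterministic.
4. **Sign alignment.** Eigenvectors are defined up to sign, so per-region
   group statistics on raw eigenvectors would be meaningless. Every subject's
   vector is flipped so that its largest-magnitude entry is positive. The
   test suite verifies that arbitrary per-subject sign flips leave all
   downstream reports bit-identical.
5. Regions whose aligned `y_opt` entries differ between groups (two-sample
   t-test, p < 0.05) become the global feature columns.

## Fusion and classification

Feature tables are fused by column concatenation (p + q columns), preserving
per-column provenance tags. Classification is evaluated under LOOCV — one
subject held out per fold, features standardized with training-fold
statistics only — with four classifiers suited to small samples: Gaussian
naive Bayes, Fisher LDA (ridge-stabilized when the within-class scatter is
singular), L2-regularized logistic regression, and a soft-margin RBF-kernel
SVM. The SVM's `C` is searched over {0.1, 1, 10, 100} and its kernel width
`sigma^2` over {0.1, 1, 10} times the median squared pairwise distance of the
training fold; the LR ridge penalty over {1, 0.1, 0.01}. Both grids are
resolved by a deterministic stratified 5-fold search *inside the training
fold*, so no information from the held-out subject leaks into tuning.

Reported metrics are ACC, Precision, Sensitivity, F1 (checked against their
defining identities to 1e-12) and AUC computed as the Mann–Whitney rank
statistic of the pooled LOOCV scores — with one score per subject, pooling is
the only coherent LOOCV AUC. Scores are oriented so that larger means more
aMCI-like; aMCI ("A") is the positive class. The report layer distinguishes
method variants `SSW` (strict threshold only — the traditional baseline),
`MGS-WBC` (dual masks) and `FUSE` (dual masks plus global features).

## The synthetic cohort generator

The generator mirrors the clinical study design this package emulates: two groups (defaults 33
and 34 subjects), 140 time points at TR = 3 s, and a 90-region Voronoi
parcellation of an ellipsoidal brain mask on a 24 x 28 x 24 grid (a
desk-scale stand-in for an MNI grid). Two kinds of ground truth are planted:

* **Cluster effects in scalar maps.** Each subject carries a scalar map with
  voxelwise-independent between-subject noise (default sd 0.1 around baseline
  1); inside a planted cluster, group A's mean is shifted by a configured
  amount in map units, so Cohen's d is exactly `shift / map_noise_sd`.
  Planting the effect directly in map units — rather than trying to steer the
  nonlinear ReHo statistic through the time series — is what makes coverage
  and false-positive criteria exactly interpretable, and voxelwise
  independence makes null calibration exactly binomial. The 4-D time series
  of affected subjects also carry a coherent low-frequency trace in planted
  clusters, so map-channel and time-series-channel analyses point at the same
  voxels, but quantitative effect-size guarantees attach to the maps. When a
  cohort provides maps, `run_pipeline()` uses them as a scalar-map channel;
  ReHo/ALFF are computed from the 4-D data when maps are absent.
* **Edge effects in connectivity.** For each planted edge, a shared latent
  time series is mixed into all voxels of the two regions, with the mixing
  weight solved per subject from the target correlation and the measured
  variance of the region-averaged noise, so the population correlation of the
  two regional means equals the target. Monte-Carlo tests check group-mean
  sample correlations to within ±0.1.

The time-series noise field is spatially smoothed (Gaussian, FWHM 2 voxels)
to mimic smoothed rs-fMRI. What the generator does **not** emulate:
hemodynamic response shapes, scanner drift and motion artifacts, physiological
nuisance signals, anatomically realistic parcel geometry, and spatial
autocorrelation of *between-subject* map noise. Passing tests therefore
demonstrate algorithmic correctness and calibration under idealized noise,
not expected performance on clinical data; the headline accuracies of the
emulated study are computed on restricted clinical data and are not
reproducible at desk scale. Two further caveats: spatial smoothing induces a
small positive baseline correlation between adjacent regions, so planted
low-correlation targets can be overshot by up to about 0.1 for neighbouring
region pairs; and effects planted through several edges sharing a region
interact additively, so exact targets hold only for disjoint pairs.

## Numerical choices

* Eigenvalues are clamped to [0, 2] (overshoot at machine precision only);
  the trivial-eigenvalue threshold is 1e-10; the `W y = 0` branch is covered
  by the `lambda = 1` eigenpairs of the same solve.
* VC's zero-mean guard is 1e-8; undefined VC locations are excluded from the
  volatility ranking, never treated as stable.
* Zero pooled variance in the t-test: equal means give `t = 0, p = 1`;
  unequal means with zero variance are an error rather than an infinity.
* Degenerate inputs error early with named offenders: atlases with missing
  labels, zero-variance regions, isolated graph nodes, correlation targets
  with `|r| >= 1`, dropping more time points than exist.
* Constant feature columns pass through standardization unscaled; SVM width
  grids fall back to 1 when all pairwise distances are zero.

## Problem sizes used in tests and the acceptance script

Oracle checks run at full fidelity (100 random graphs, 1,000 VC vectors, all
10,625 confusion matrices with at most 20 subjects). Recovery and calibration
checks use 30 subjects per group on the default 24 x 28 x 24 grid for
map-space analyses, and 30 per group on a 12 x 14 x 12 grid with 140 time
points for the end-to-end classification runs — small enough to generate
fresh cohorts in seconds while keeping per-voxel power near 1 for the planted
d = 2 effects. Null-calibration rates are pooled across seeds so the binomial
reference bounds are tight.

## Known limitations

* Feature selection on the full cohort (the emulated design) is optimistic;
  nothing in the LOOCV protects against selection bias. Treat absolute
  synthetic accuracies as a check of separability recovery, not as estimates
  of clinical performance.
* The Voronoi atlas has no anatomical meaning; region names in reports are
  placeholders (`region_01` ...) unless real atlas names are supplied.
* Coordinates are reported in voxel indices for synthetic data; supplying
  data with a real affine shifts the convention to millimetres in the header
  of the cluster reports.
* Single global vector only: the method reduces each network to one
  eigenvector; multi-dimensional spectral embeddings are out of scope.
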