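---
title: "Methods: predicting MCI-to-AD conversion from hippocampal 2.5D patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting MCI-to-AD conversion from hippocampal 2.5D patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Mild cognitive impairment (MCI) is the prodromal stage of Alzheimer's
disease (AD); a fraction of MCI patients convert to AD within a few years
while others remain stable. `mci25d` implements an MRI-only prediction
pipeline for this converter / non-converter distinction. Its premise is
that the morphological changes separating converters from non-converters
are a milder version of those separating AD patients from normal controls
(NC), concentrated around the hippocampus. The pipeline therefore:

1. **normalizes intensities** by monotone quantile mapping of each
   subject's histogram onto a template's;
2. **removes normal aging effects** with a per-voxel linear model
   $y_m = \omega_m \alpha + b_m$ fit across healthy subjects, shifting
   every subject to a common reference age $C$ via
   $y'_{mn} = \omega_m (C - \alpha_n) + y_{mn}$ (default $C = 75$ years);
3. **samples 151 fixed locations** inside a binary hippocampus mask, each
   pair more than 2 voxels apart, and assembles a **2.5D patch** per
   location: three orthogonal 32×32 windows (transverse, coronal,
   sagittal) stacked as the channels of one 32×32×3 array;
4. **trains a small CNN on AD/NC patches only** — conv 5×5 (pad 2) →
   ReLU → max-pool 3×3/2 → LRN, twice more with average pooling, spatial
   trace 32→16→8→4, ending in 64 maps of 4×4 whose flattened 1024 values
   are the *deep features* of a patch — and transfers it, frozen, to MCI
   subjects (1024 × 151 = 154 624 deep values per image);
5. **reduces and selects**: PCA to $P_C = 29$ components per patch
   (pooled over training subjects' patch rows), concatenation of the 151
   patch blocks, and least-angle-regression LASSO stopped after exactly
   $L_C = 35$ entries; structural (FreeSurfer-style, 325-column) features
   go through PCA to $P_F = 150$ and LASSO to $L_F = 40$; the fused
   vector has $35 + 40 = 75$ features;
6. **classifies with a kernel extreme learning machine (ELM)**:
   $\beta = (\Omega + I/C)^{-1} y$ with RBF kernel
   $\Omega_{ij} = \exp(-\gamma \lVert x_i - x_j \rVert^2)$ and
   regularization $C = 1$; the decision value
   $f(x) = k(x)^\top \beta$ also feeds the ROC;
7. **evaluates** under leave-one-out or stratified k-fold
   cross-validation, refitting standardization, PCA (by default), LASSO
   and the classifier inside every fold. The positive class is the MCI
   converter throughout.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `reference_age` | 75 y | common age all subjects are shifted to |
| `n_locations` | 151 | patches per image (fixed across subjects) |
| `min_distance` | 2 voxels | pairwise spacing of patch centers (strict `>`) |
| `channels` | 32/32/64 | CNN feature maps per stage |
| `momentum / lr / decay` | 0.9 / 0.001 / 1e-4 | SGD recipe |
| `epochs / batch_size` | 30 / 151 | training schedule |
| `p_c, p_f, l_c, l_f` | 29, 150, 35, 40 | PCA / LASSO widths |
| `lambda` | 0.1 | LASSO penalty context (the L-step stop is operative) |
| `reg_c` | 1 | ELM regularization |
| `gamma` | 1/d | RBF width on standardized features |

The second conv stage's channel count and the LRN constants are not
pinned by the architecture description; we use the classic 32/32/64
small-image stack and conventional LRN defaults (size 3, α = 5e-5,
β = 0.75, k = 1), all exposed in `cnn_config()`. The classification head
is a single 2-unit fully connected layer with softmax.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` renders phantoms on a common 64³ grid: a soft-edged
"brain" ellipsoid plus two ellipsoidal hippocampi. Disease is an ordered
reduction of hippocampal intensity (defaults AD 0.30 > MCIc 0.18 >
MCInc 0.08 > NC 0, i.e. AD loses about a third of hippocampal contrast —
a deliberately coarse surrogate for gray-matter loss) together with a
mild shrinkage of the bright core; normal aging is a linear intensity
trend (−0.004 units/year against ~0.45 units of contrast, ≈ 0.9 %/year,
in the range of reported hippocampal atrophy rates); noise is i.i.d.
Gaussian (SD 0.05). Group sizes default to the clinical cohort the
pipeline targets (188/229/169/139) and ages are uniform on 55–91 years.
One mask is shared by the cohort, as with an overlapped segmentation.
The structural table has 325 columns of which the first 40 carry a group
shift (MCIc vs MCInc separated by `struct_effect_size` pooled SDs, AD vs
NC by twice that) plus an age trend; the rest are standard normal noise.

Not emulated: MRI physics (bias fields, partial volume), registration
error, per-subject anatomy, correlated structural features, site
effects. A green test therefore establishes that the *pipeline machinery*
behaves as specified under its own statistical assumptions — it says
nothing about clinical accuracy, and the published ADNI performance
numbers are out of scope by design.

## Numerical and protocol choices

* **Indexing.** R is 1-based, so voxel indices are 1-based with axis
  order (x, y, z); transverse = fixed z, coronal = fixed y, sagittal =
  fixed x. A 32-window spans `[c-16, c+15]`; the center sits at position
  17 (offset 16 from the window start).
* **Pooling** uses ceil-mode 3×3/2 windows clipped at the border (so
  32→16→8→4); averages divide by the clipped window size. Max-pool ties
  route the gradient to the first maximal element.
* **Aging model** is fit on NC subjects only — fitting on all
  non-demented subjects would leak disease effects into the model.
* **LARS stopping.** The path stops as soon as the L-th distinct
  variable enters, making selections for smaller L exact prefixes; the
  quoted penalty λ = 0.1 is carried as context. If the path exhausts
  (rank/sample-size limit) before L entries, that is an error, not a
  silent truncation.
* **ELM solve.** $(\Omega + I/C)$ is symmetric positive definite for any
  $C > 0$, so a Cholesky solve is used; the closed form is taken as the
  matrix inverse applied to $y$ (the printed formula's transpose is
  vacuous for symmetric $\Omega$).
* **PCA scope.** By default PCA is refit inside every CV fold, like
  standardization and LASSO (leak-free). `pipeline_params(pca_scope =
  "global")` fits it once on all subjects before CV — the likely
  protocol of the original experiments and substantially cheaper; it is
  used by the heavy acceptance runs and labeled as such.
* **CNN transfer.** The CNN (and the volumetric aging model) are fit
  once per experiment, outside the CV loop, because they train on AD/NC
  and never see MCI labels. This is weaker than full nested CV and is
  stated prominently for that reason.
* **Patch-vote ties** go to the positive class; with the default 151
  (odd) patches ties cannot occur.
* **Determinism.** Every stochastic step (cohort, locations, weight
  init, epoch shuffles, fold shuffles, bootstrap) is governed by an
  explicit seed; identical configurations reproduce results bit-for-bit.

## Build-vs-buy notes

The target environment provides no R NIfTI reader, no deep-learning
framework, no `lars`, and no SVM / random-forest package. Consequently:
NIfTI-1 I/O is implemented minimally in base R (cross-validated against
nibabel during development); the CNN is implemented in R with
Rcpp kernels for im2col/col2im and pooling (validated by
finite-difference gradient checks); LARS-LASSO is implemented in-package
and checked against glmnet at matched penalties; and the comparison
baselines are an in-package L2-SVM (BFGS on the squared hinge) and a
compact Gini CART bagging forest, run through the identical CV harness.

## Known limitations

* The strong-effect acceptance world (atrophy gap 0.5, structural effect
  1.5 SD) is *more* separable than clinical data: all feature routes
  saturate at AUC 1.0, so the "fused strictly beats each single route"
  comparison degenerates to a tie at the ceiling. The weak ordering
  (fused never worse) holds in every run; the strict form is left
  failing rather than tuning the generator after the fact.
* Training the published 30-epoch, 62 967-patch schedule takes hours on
  one CPU in this implementation; tests and examples use reduced channel
  counts, epochs and patch counts, which preserve every structural
  property but not the original training dynamics.
* Histogram matching uses 256 quantile anchors with linear
  interpolation; exact invertibility at duplicated quantiles is not
  guaranteed (ties collapse to the mean template quantile).
* Volumes must share one grid; there is no resampling, registration or
  skull stripping — those are upstream of this package by design.
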