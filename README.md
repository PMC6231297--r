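# mci25d

Predicting conversion from mild cognitive impairment (MCI) to Alzheimer's
disease (AD) from structural MRI, for researchers who want a tested,
reusable R implementation of the hippocampus-patch CNN + kernel-ELM
pipeline — and a synthetic phantom cohort so every stage runs without
access-controlled clinical data.

## The method

Subjects' template-space volumes are intensity-normalized by histogram
matching and corrected for normal aging with a per-voxel linear model
*y*<sub>m</sub> = ω<sub>m</sub>α + *b*<sub>m</sub> fit on healthy
controls; each subject is shifted to a common reference age *C* = 75 by
*y*′<sub>mn</sub> = ω<sub>m</sub>(*C* − α<sub>n</sub>) + *y*<sub>mn</sub>.
151 fixed locations are sampled inside a hippocampus mask (pairwise
distance > 2 voxels); each yields a **2.5D patch**: three orthogonal
32×32 windows (transverse / coronal / sagittal) stacked as channels. A
small CNN — conv 5×5 (pad 2) → ReLU → pool 3×3/2 (max, avg, avg) with
LRN, spatial trace 32→16→8→4 — is trained on AD vs normal-control
patches with momentum SGD (0.9 / 0.001 / 10⁻⁴, 30 epochs, batches of
151) and transferred, frozen, to MCI subjects; the flattened last-pool
output provides 1024 deep features per patch (1024 × 151 = 154 624 per
image). Deep features are reduced per patch by PCA (*P*<sub>C</sub> = 29),
concatenated, and pruned by least-angle-regression LASSO
(min ½‖y − Dα‖² + λ‖α‖₁, stopped after *L*<sub>C</sub> = 35 entries);
a 325-column structural (FreeSurfer-style) table goes through PCA
(*P*<sub>F</sub> = 150) and LASSO (*L*<sub>F</sub> = 40). The fused
75-feature vector is classified by a kernel extreme learning machine,
β = (Ω + I/C)⁻¹y with RBF kernel and C = 1, under leave-one-out or
stratified k-fold cross-validation (fold-local refits of
standardization, PCA, LASSO and the classifier). Positive class = MCI
converter; metrics are accuracy, sensitivity, specificity and
trapezoidal AUC.

See `vignettes/methods.Rmd` for assumptions, parameter rationale and
limitations.

## Worked example

```r
library(mci25d)

cfg <- experiment_config(
  synth = synthetic_config(
    n_per_group    = c(AD = 10, NC = 10, MCIc = 12, MCInc = 12),
    atrophy_effect = c(AD = 0.8, MCIc = 0.55, MCInc = 0.15, NC = 0),
    struct_effect_size = 1.2, seed = 1),
  cnn    = cnn_config(channels = c(8, 8, 16), epochs = 3, seed = 2),
  params = pipeline_params(p_c = 6, p_f = 10, l_c = 8, l_f = 6,
                           pca_scope = "global"),
  n_locations = 20, seed = 3)

res <- run_experiment(cfg, verbose = TRUE)
res$eval
```

prints (elided):

```
training CNN on 400 AD/NC patches
extracting deep features for 24 MCI subjects
running loocv cross-validation over 24 MCI subjects
<eval_result> n=24  acc=1.000  sens=1.000  spec=1.000  auc=1.000
```

Every MCI subject is held out once; its score is the ELM decision value
of a model refit without it. On this deliberately strong-effect phantom
cohort (55 % vs 15 % hippocampal signal loss, 1.2 SD structural shift)
separation is perfect — the phantoms are far easier than clinical data,
which is exactly what makes them useful for verifying the machinery.
`res$eval$per_subject` holds the per-subject truth/prediction/score
table and `res$eval$roc_points` the ROC.

Stage functions are exported individually (`generate_cohort`,
`match_histogram`, `fit_age_correction`, `sample_locations`,
`extract_patch`, `build_cnn`, `train_cnn`, `extract_cnn_features`,
`fit_pca`, `lars_lasso_select`, `train_elm`, `loocv`, `kfold_cv`, ...),
and `inst/cli/mci25d` provides `synth` / `patches` / `agecorrect` /
`run` subcommands driven by a YAML config.

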