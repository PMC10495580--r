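# specqc — automated quality control of 3D MRSI voxel spectra

3D MR spectroscopic imaging (MRSI) produces a spectrum for every brain
voxel — thousands per scan — and each must be checked for quality (SNR,
linewidth, lipid contamination, residual water) before metabolite maps can
be trusted. Expert labeling takes 10–15 minutes per dataset; `specqc`
automates it with voxel-wise good/bad classifiers, and ships everything
needed to exercise and evaluate them end-to-end on simulated cohorts when
clinical data is unavailable.

The package provides:

* **Preprocessing** — real-part extraction, cropping to the closed
  1.4–4.1 ppm window (850 points), per-spectrum z-normalization
  (`preprocess()`).
* **Consensus labeling** — a voxel is *good* only if both raters say so
  (`aggregate_labels()`).
* **Five classifiers** behind one fitting front-end (`qc_fit()`):
  a 200-tree random forest on raw spectra (mtry = ⌊√850⌋ = 29); a 6-layer
  1D CNN (6 × conv/ReLU/max-pool, two FC layers, 64-node penultimate,
  softmax); an inception CNN (2 conv blocks + 2 inception modules with
  kernel-1/3/5 and pooled branches); and the CNN+RF / ICNN+RF hybrids — a
  200-tree forest on the network's 64 penultimate features (mtry = 8).
  Networks train with Adam, learning rate 1e-4, batch 64, 15 epochs,
  categorical cross-entropy. The conv/backprop/Adam engine is implemented
  in base R with BLAS matrix products and finite-difference-verified
  gradients.
* **Subject-grouped cross-validation** (`make_split_plan()`,
  `run_cross_validation()`): a rotating scheme holding out 4 test + 4
  validation subjects (one per cohort type) per fold, repeated 10 times
  without test replacement, and a leave-one-subject-out scheme with
  2-subject validation sets; subject leakage between partitions is
  asserted, never assumed.
* **Metrics** (`roc_auc()`, `pr_auc()`, `qc_accuracy()`,
  `subset_report()`, `aggregate_folds()`): midrank Mann–Whitney ROC-AUC,
  tie-grouped average precision, thresholded accuracy, lesion-only (T2L)
  subset reports, mean ± sd fold aggregation.
* **Integrated gradients** (`integrated_gradients()`,
  `attribution_mask()`): midpoint-Riemann path attributions for the
  network models, with the completeness residual recorded on every result.
* **A synthetic cohort simulator** (`generate_cohort()`): Lorentzian
  metabolite lines (NAA/Cr/Cho/Glx/mI), frequency shift, linewidth
  broadening, edge-truncated lipid and residual-water artifacts, Gaussian
  noise, two simulated raters with near-threshold jitter, and a
  `severity_separation` dial running from exactly separable classes to
  pure label noise.

See `vignettes/spectral-qc-methods.Rmd` for the model, simulator and
evaluation details and the reasoning behind every open design choice.

## Worked example

```r
library(specqc)

coh <- generate_cohort(sim_config(n_subjects = 12, voxels_per_subject = 40,
                                  severity_separation = 0.9, seed = 7))
coh
#> <qc_cohort> 480 voxels from 12 subjects, 850 axis points
#>   consensus labels: 265 good / 215 bad (55:45)
#>   subjects per cohort tag: healthy=3, MDD=3, MS=3, PD=3

pp <- preprocess(coh)
plan <- make_split_plan(pp, "nd_rotating", seed = 7, n_repeats = 3)
cv <- run_cross_validation(pp, model_spec("rf"), plan = plan, seed = 7)
cv
#> <qc_cv> rf model, nd_rotating scheme, 3 fold(s)
#> Aggregate over 3 fold(s):
#>   auc       0.933 +/- 0.005
#>   auc_pr    0.914 +/- 0.019
#>   accuracy  0.904 +/- 0.022
```

The simulated cohort lands at the requested ~55:45 good:bad balance; at
separation 0.9 (realistic rater consistency) a raw-spectrum random forest
reaches held-out AUC ≈ 0.93 across three subject-disjoint folds — good
discrimination, with the remaining errors coming from near-threshold
voxels and rater label noise. At `severity_separation = 1` every model
kind exceeds AUC 0.95, and at `0` all fall to chance; both ends are
enforced by the test suite.

A command-line front-end covering
simulate / preprocess / train / predict / cv / evaluate / attribute lives
at `inst/cli/specqc.R`:

```sh
Rscript inst/cli/specqc.R simulate --out cohort --subjects 12 --voxels 40 --seed 7
Rscript inst/cli/specqc.R preprocess --in cohort --out cohort_pp
Rscript inst/cli/specqc.R cv --cohort cohort_pp --model rf \
        --scheme nd_rotating --repeats 3 --seed 7 --out results/
```

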