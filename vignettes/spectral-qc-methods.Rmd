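---
title: "Methods: automated quality control of MRSI voxel spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated quality control of MRSI voxel spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specqc)
```

## The problem

3D MR spectroscopic imaging (MRSI) of the brain yields one spectrum per
spatial voxel — thousands per examination. Before metabolite maps can be
interpreted, each voxel must pass quality control: enough signal-to-noise,
acceptable linewidth, no scalp-lipid contamination, adequate water
suppression. Done manually by experts this takes 10–15 minutes per dataset
and is the main bottleneck for clinical use. `specqc` implements an
automated, voxel-wise good/bad classifier family for this task, together
with the subject-grouped evaluation machinery needed to measure it
honestly, and a synthetic cohort simulator so that the whole pipeline can
be exercised end-to-end without access to clinical data.

Labels follow the conservative two-rater consensus convention: a voxel is
*good* only if both raters call it good; a voxel flagged by either rater is
*bad*. `aggregate_labels()` is this AND rule, and every simulated cohort
carries per-rater verdicts plus the derived consensus.

## Preprocessing

Model input is produced by a fixed chain (`preprocess()`):

1. **real part** of the complex signal (`take_real()`),
2. **crop** to the closed window 1.4–4.1 ppm (`crop_to_window()`), 850
   points on the canonical axis,
3. **z-normalization** per spectrum to mean 0, standard deviation 1
   (`znormalize()`).

Three conventions here were genuinely open and are package decisions: the
crop interval is *closed* (both bounds kept); the standard deviation is the
population (divide-by-*n*) estimator; and zero-variance spectra are
rejected rather than zero-filled, since no constant vector can satisfy the
normalization contract. Axes are always stored ascending in ppm; the NMR
display convention (ppm decreasing left-to-right) is applied only at plot
time, keeping indexing unambiguous. The canonical simulator axis has
exactly 850 uniform points on [1.4, 4.1] ppm so network input length needs
no resampling; real acquisitions on other grids are cropped and then
linearly resampled to 850 points — a documented extension beyond the core
contract.

## The five classifiers

All five take the same preprocessed 850-point spectrum:

* **rf** — a random forest of 200 trees on the raw spectral points, with
  `floor(sqrt(850)) = 29` candidate features per split. (Some conventions
  round the square root to 30; the value is a `model_spec` field, so either
  choice is reproducible.)
* **cnn** — six blocks of (1D convolution → ReLU → max-pool 2), then two
  fully connected layers, the second with 64 nodes, then a two-class
  softmax head.
* **icnn** — two (convolution → ReLU → max-pool) blocks, then two
  inception modules, each a channel-concatenation of parallel kernel-1/3/5
  convolution branches plus a width-3 max-pooled branch projected by a 1×1
  convolution, each module followed by max pooling; then the same
  fully-connected tail.
* **cnn_rf / icnn_rf** — hybrids: the trained network's 64-node
  penultimate activations become the feature vector of a 200-tree random
  forest (`floor(sqrt(64)) = 8` features per split), which produces the
  final prediction.

The layer *counts*, the 64-node penultimate width, and the tree counts are
contracts; kernel sizes, channel widths, pooling widths and activations
are not, and default to conventional 1D-CNN choices (kernel 5, pooling 2,
channels doubling 16→512 across the six CNN blocks, ICNN conv blocks
16→32 with 16 channels per inception branch, first FC width 256, ReLU
throughout, no dropout or batch normalization). All of these are
`model_spec()` fields. The examples, tests and acceptance script run with
reduced channel widths (4–32) — the synthetic task needs far less capacity
than the clinical-scale defaults, and the architecture contracts are
width-independent.

The network engine is implemented in base R: convolutions are im2col patch
matrices multiplied by weight matrices (BLAS does the work), gradients are
exact backpropagation verified against finite differences, and the same
backward pass propagates to the input, which is what integrated gradients
needs. Training uses Adam (learning rate 1e-4, batch 64, 15 epochs,
categorical cross-entropy) with per-epoch loss/accuracy curves on the
training and validation sets; the final-epoch weights are kept — no early
stopping and no best-epoch checkpointing, since the protocol fixes the
epoch count and uses validation curves only as diagnostics. Batches are
reshuffled each epoch with a seeded generator and the last partial batch is
kept. "Good" is the positive class everywhere, and accuracy thresholds
probabilities at 0.5, which coincides with argmax for a two-class softmax.

## Subject-grouped cross-validation

Voxels from one subject are strongly correlated, so folds split *subjects*,
never voxels (`make_split_plan()`), and the trainer refuses
training/validation sets that share subjects:

* **nd_rotating** — each fold holds out 4 test subjects (one per cohort
  tag: healthy, MDD, MS, PD) and 4 validation subjects (likewise one per
  tag); the rest train. Ten repeats use a seeded within-tag permutation so
  each subject is tested at most once — the protocol only says "a
  different set of patients" per repeat, and without-replacement rotation
  is this package's reading.
* **bt_leave_one_out** — one fold per subject (13 in a tumor cohort of
  13): that subject tests, two validation subjects are redrawn per fold
  with a per-fold seed, the rest train.

Each fold reports ROC-AUC, precision-recall AUC and accuracy on the test
subjects only; `aggregate_folds()` gives mean ± sample (n−1) standard
deviation across folds, with a single fold reporting sd 0 by convention.
Tumor cohorts additionally report the lesion-only (T2L) subset per fold.

ROC-AUC is the midrank Mann–Whitney statistic (ties credited 0.5). AUC-PR
is *average precision* with tied scores processed as one threshold group —
step interpolation, not trapezoidal PR interpolation, which is biased
upward; this is stated so numbers are comparable across implementations.
On a single-class subset the AUC metrics are undefined and reported as
`NA` with a warning, while accuracy is still computed.

## The synthetic cohort simulator

`generate_cohort()` emulates the *structure* of short-echo brain MRSI
spectra in the analysis window, not their quantitative physics:

* **Clean spectra** are sums of Lorentzian lines for the dominant
  metabolites — NAA (2.01 ppm, amplitude 1), creatine CH3/CH2 (3.03/3.93),
  choline (3.22), plus broad Glx (2.35) and myo-inositol (3.56)
  contributions — with per-voxel log-normal amplitude jitter (σ = 0.08)
  and ±10% linewidth jitter around a 0.035 ppm nominal FWHM.
* **Artifacts** enter in a fixed order: circular frequency shift;
  linewidth broadening by convolution with an area-preserving Lorentzian
  kernel (kernel FWHM = (factor − 1) × nominal, so final linewidths scale
  by the factor); lipid contamination as a broad 1.3 ppm resonance
  truncated at the 1.4 ppm edge; residual water as the down-field tail of
  a 4.7 ppm line entering at the 4.1 ppm edge — both artifact centers lie
  at or beyond the window edges, which is exactly how they appear inside
  the analysis window; and additive Gaussian noise. Severity-1 ranges
  (noise σ up to 0.15 of the NAA amplitude, broadening up to 3.5×, lipid
  up to 2.2, water up to 1.8) were chosen once as representative of badly
  failed voxels.
* **Labels.** Each voxel draws an intended class (Bernoulli
  `fraction_bad`, default 0.46 to match a roughly 54:46 good:bad balance;
  tumor-style cohorts use 0.29 for 71:29) and a latent severity *S*
  consistent with it around the cut 1 − `fraction_bad`; one of the four
  criteria (noise, broadening, lipid, water) is made dominant at severity
  *S* and the others draw a random fraction of it, so the worst-criterion
  rule "bad iff any criterion exceeds its threshold"
  (`assign_truth_label()`) recovers the class. Raters judge a *perceived*
  severity that equals the true one with probability
  `severity_separation` and is otherwise an independent redraw from the
  same marginal; near-threshold verdicts flip with probability up to
  `rater_noise` inside a ±0.1 band. Consequences, all tested: at
  separation 1 the classes are exactly separable by a threshold on the
  severity score with a clean 0.15 margin; at separation 0 the labels are
  statistically independent of the spectra while the class balance is
  preserved; and the realized bad fraction tracks `fraction_bad` within
  binomial noise at every separation. This decoupling is deliberate — the
  three constraints cannot all be met by thresholding the true profile
  alone.
* **Tumor mode** tags all subjects as tumor, flags ~19.5% of voxels as
  lesion (T2L), and gives lesion voxels suppressed NAA (×0.35) and
  elevated choline (×1.8) — the metabolic signature that makes tumor
  spectra atypical.
* **Reproducibility.** One master seed draws per-subject seeds, and each
  subject's voxels are generated under its own seed, so cohorts are
  bit-identical across runs and subjects are reproducible in isolation.

What the simulator does **not** model: J-coupling multiplet structure,
Voigt/Gaussian lineshape components, B1 inhomogeneity, chemical-shift
misregistration, spatially structured artifacts, and rater drift. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline learns
and evaluates correctly under the simulated artifact taxonomy — they are
not evidence about accuracy on clinical 7T data, whose headline numbers
require the private cohorts.

## Integrated gradients

For the network models, `integrated_gradients()` attributes a prediction
to spectral points: attribution_i = (x_i − b_i) × the mean gradient of the
predicted-class probability along the straight path from baseline *b* to
input *x*, discretized with a midpoint Riemann rule (default 256 steps).
Decisions: the baseline defaults to the all-zero spectrum in normalized
space (a dataset-mean baseline is available); attribution targets the
*predicted* class, which is what one inspects on mispredicted voxels; and
the completeness residual |Σ attribution − (F(x) − F(b))| is recorded on
the result, never hidden. The completeness axiom is tested to hold within
2% at 256 steps on trained CNNs (ReLU kinks keep the path integral from
converging faster), the zero-path and linear-model closed forms hold
exactly, and `attribution_mask()` rescales |attributions| to max 1 (an
all-zero attribution yields an all-zero mask rather than 0/0).

## Numerical and degenerate-input choices

* Cropping errors name the uncovered window side; cohort containers
  validate their manifest schema and name the offending field.
* Constant (zero-variance) spectra fail z-normalization explicitly.
* An empty peak list yields a flat clean spectrum (allowed, degenerate);
  it becomes usable only once noise is injected.
* `roc_auc` refuses single-class inputs; `pr_auc` refuses
  positive-free inputs; accuracy refuses empty inputs.
* Max-pooling keeps the floor of half the length (odd tails dropped);
  ties in pooling take the earlier index; `max.col` ties resolve to the
  first column.
* Learning rate 0 is allowed and provably leaves parameters untouched
  (used as the zero-step optimizer check).

## Problem sizes used by the shipped runs

The test-suite and acceptance-script runs are sized for a single CPU:
simulated cohorts of 10–40 subjects with 20–100 voxels each, reduced
channel widths (4–32), and 5–15 epochs. The acceptance script evaluates
all five model kinds on one rotating fold of a 16-subject × 60-voxel
separable cohort with 15 epochs, a chance-level random-forest control on a
separation-0 cohort of the same size, and a 256-step completeness check.
These sizes are the package's own choices for a desk-scale demonstration;
the architecture, optimization and evaluation contracts they exercise are
size-independent.

## Known limitations

* The network engine is CPU-only, double precision, single-threaded apart
  from BLAS; clinical-scale channel widths (16→512) train in minutes–hours,
  not seconds.
* Random-forest determinism is platform-dependent only through R's RNG;
  network training is deterministic to ~1e-5 across runs on the same
  platform (BLAS summation order).
* The simulator's artifact thresholds are simulator parameters, not claims
  about clinical rater criteria, for which no quantitative thresholds are
  published.
* Attribution is defined for the differentiable models only; tree and
  hybrid models are out of scope by design.
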