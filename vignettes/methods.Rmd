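---
title: "Predicting axillary nodal status from mammograms: models, phantom data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting axillary nodal status from mammograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

In clinically node-negative (cN0) early breast cancer, sentinel lymph node
biopsy (SLNB) is the standard surgical staging of the axilla, yet roughly
seven of ten cN0 patients turn out node-negative and gain no therapeutic
benefit from the procedure. A preoperative prediction model that identifies
low-risk patients could let surgery be omitted for them; the share of
patients a deployed model would spare is the *SLNB reduction rate*,
`(TN + FN) / n`. `mammonode` implements, at desk scale, a three-step
deep-learning workflow for this problem: mammography carries indirect
evidence of nodal involvement — tumor size, multifocality, peritumoral
tissue changes — that routine full-breast images capture and that
region-of-interest (ROI) crops around the index lesion may miss.

The three steps are:

1. **Self-supervised pretraining** of a residual convolutional backbone on
   unlabeled image patches (Barlow Twins by default; BYOL and SwAV are
   implemented as alternatives).
2. **Multi-task supervised training of a neck module** — residual blocks
   or a small vision Transformer — over the backbone's spatial feature
   map, predicting five postoperative outcomes per image: LNM status,
   number of metastatic nodes, lymphovascular invasion (LVI), pathological
   tumor size, and multifocality.
3. **Patient-level fusion**: image-level predictions are averaged over
   cross-validation models, maximized over views, concatenated with 11
   encoded preoperative clinical variables, and fed to a one-hidden-layer
   MLP that emits the final LNM probability.

Everything is evaluated with nested (double) cross-validation and a
decision-analytic metric layer.

## The phantom cohort

The real cohorts behind this workflow are private. The package therefore
ships a seeded synthetic generator (`cohort_config()`, `generate_cohort()`,
`render_mammogram()`) whose **clinical table** reproduces the published
development cohort's conditional structure: 30% LNM prevalence;
pathological tumor size truncated-normal on (0, 50] mm with conditional
means 18.9 mm (node-positive) / 14.2 mm (node-negative) and SD 8.1 mm; LVI
positive rates 33%/11% by nodal status; multifocality 34%/19%; number of
metastatic nodes 0 for node-negative patients and `1 + NB` with mean 2.4
and SD 2.8 among positives (a negative binomial absorbs the printed
overdispersion that a Poisson cannot match); younger, more often
premenopausal and symptomatically detected node-positive patients; and
per-variable missing-completely-at-random rates mirroring the published
missing counts (e.g. LVI about 12.5%). The St Gallen surrogate subtype is
derived from the simulated ER/PgR/HER2/Ki67 markers rather than drawn
independently, so marker-subtype consistency holds by construction; its
marginal distribution is therefore implied, not fitted. A
`null_associations` switch draws everything except LNM itself from pooled
marginals, which calibrates type-I-error behavior of the univariable
statistics.

The **images** are phantoms, not synthetic mammograms: a breast-shaped
half-ellipse with low-frequency parenchymal texture; one bright elliptical
lesion per focus with major axis `tsize * px_per_mm` pixels (satellite
foci when multifocal); and a radial spiculation halo around the index
lesion whose amplitude grows with LNM and LVI status, scaled by
`peritumoral_signal_strength` and extending well beyond a tumor-ROI crop.
The halo is a *modeling device* that plants an image-level nodal-status
signal outside the ROI — nothing is claimed about real mammographic
biology of node-positive disease. Consequences for interpretation: passing
direction checks show that the pipeline can discover and exploit
peritumoral image signal when it exists and that full-image models can use
evidence ROI models cannot; they do not show that real mammograms carry
such signal at any particular strength. Geometry is deterministic in
(patient, view, seed), with per-view rotation/translation jitter.
Desk-scale defaults are 384 x 256 px at 2 px/mm (the experiments below use
96 x 64 px at 1 px/mm); images are written as 16-bit grayscale PNG.

## Preprocessing

Supplementary-level preprocessing details of the original workflow are not
public, so the package fixes documented defaults: global Otsu thresholding
plus largest connected component for breast segmentation; percentile-clip
(1st-99th inside the mask) min-max intensity normalization with the
background forced to zero; contiguous (stride = size) patch tiling with a
minimum tissue fraction of 0.25 for pretraining; and zero-padded
fixed-size ROI crops (500 x 500 px at full scale) centered on the lesion
annotation — zero padding rather than reflection keeps lesion contrast
statistics unbiased at borders.

## Networks and training

There is no deep-learning runtime in the package's dependency stack, and
the training objectives *are* the method, so `mammonode` carries a small
reverse-mode autodiff engine over base-R arrays (BLAS matrix products via
offset-loop convolutions; fused, hand-derived backward rules for
convolution, depthwise convolution, layer normalization, masked softmax
attention, pooling and the masked losses — all verified against finite
differences in the test suite) plus an AdamW optimizer.

* **Backbone**: a residual convolutional encoder; each stage halves
  resolution (stride-2 3x3 conv + residual 3x3 conv). Desk default
  channels (8, 16, 32); the channel count of the last stage is the
  feature dimension (1024 at the full scale the workflow describes).
* **SSL objectives**: Barlow Twins (`lambda = 0.005`), BYOL (EMA momentum
  0.996), SwAV (epsilon 0.05, 3 Sinkhorn sweeps; sweeps continue to a
  1e-8 marginal tolerance so the transport-plan contract holds
  regardless of score scale). Augmentations: random resized crop, flips,
  intensity jitter, Gaussian blur.
* **ResBlock neck**: 1 block for ROI input, 2 for full images; each block
  is a 1x1 bottleneck (feature_dim/8 channels, mirroring the 1024 to 128
  narrowing), depthwise 3x3, 1x1 expansion, identity skip; global average
  pooling produces the representation.
* **Transformer neck**: shifted patch tokenization (concatenation of the
  map with its four diagonal unit shifts, layer norm, linear projection,
  class token, positional embeddings) and locality self-attention
  (learnable temperature initialized at sqrt(d_head), self-token masked to
  -Inf), pre-norm blocks, class-token readout. Class-token readout rather
  than mean pooling follows the small-dataset ViT lineage these
  modifications come from. Desk defaults: depth 1-2, 2 heads, dim 32.
* **Heads and loss**: five linear heads; sigmoid for the three
  classifications; regressions in transformed space — `log1p` for node
  counts, size/50 for tumor size — with exact inverses. The multi-task
  loss masks missing labels to zero contribution and normalizes each task
  by its observed count, so an all-missing sample leaves gradients
  unchanged (asserted in tests); task weights are equal by default since
  no weighting is published. Backbone weights are finetuned during
  supervised training by default (`freeze_backbone` flips this; the
  original report does not say which was used).
* **Fusion MLP**: one hidden layer of 128 units, dropout 0.2, AdamW,
  learning rate 0.01, weight decay 1e-4, batch size 32 — the printed
  hyperparameters, kept as defaults. Age and BMI are z-scored and median-
  imputed with statistics from training folds only; categoricals are
  binary/one-hot with per-variable missing indicators (29 numbers in
  total). LVI never enters the encoding: it is an outcome.

## Double cross-validation and evaluation

`make_plan()` builds stratified 5 x 5 nested folds (LNM is the only
stratification key; site or year labels exist only synthetically):
inner folds drive early stopping, outer folds give every development
patient an out-of-fold prediction, and 25 (outer, inner) model slots form
the test-time ensemble. Prediction provenance is recorded and
machine-audited (`audit_provenance()`): no patient may be predicted by a
slot that saw them in fitting. Patient-level mammogram features follow the
fixed aggregation order *mean over models, then max over views* — the
order is asserted by a constructed counterexample in the tests.

The evaluation layer implements: Mann-Whitney ROC AUC with half-credit
ties; step-interpolated average precision; Pearson r for regressions;
operating thresholds chosen as the *largest* score threshold with
sensitivity at or above 90% (predict positive iff score >= t, closed on
the positive side; the threshold is selected once on the evaluation set
and held fixed across bootstrap resamples); specificity/PPV/NPV/accuracy
with undefined 0/0 ratios flagged rather than silently zeroed; SLNB
reduction rate; net benefit `tp/n - fp/n * pt/(1-pt)` with treat-all and
treat-none reference curves; equal-width-bin calibration curves;
patient-level bootstrap (1000 samples at full scale) with shared resample
indices across models, reversed-percentile confidence intervals
`[2T - Q(0.975), 2T - Q(0.025)]`, and single-class resamples redrawn so B
effective samples remain; and a paired two-model permutation test that
swaps the two models' predictions within patients with probability one
half (`p = (1 + #{|d| >= |d_obs|}) / (B + 1)`). Swapping paired
predictions, rather than permuting labels, is the standard two-model
comparison and was chosen because the original text does not specify the
scheme.

Univariable statistics follow the published conventions exactly: Welch's
t-test, Pearson's chi-square *without* continuity correction (the
published HER2 p-value 0.514 matches only the uncorrected statistic), and
a **df-scaled Cramer's V**, `V = sqrt(chisq / (n * df))` with
`df = (r-1)(c-1)`. The df-scaled form — identical to classical V on 2x2
tables — is the only variant that reproduces the published three-level and
four-level effect sizes (0.054, 0.058, 0.064), and it pairs with the
df-dependent nontriviality thresholds 0.30/0.21/0.17. Printed Cohen's d
values cannot be recomputed exactly from rounded group summaries and the
SD convention is ambiguous (the tumor-size value matches the whole-sample
SD, the age value sits between conventions), so both pooled (default) and
whole-sample conventions are implemented and d is not used as an exact
check.

Interpretation uses permutation-sampling Shapley values (marginal
contributions along random feature permutations against sampled background
rows; efficiency holds by telescoping), reported as mean absolute
attribution per feature averaged across cross-validation models — with the
two mammographic LNM features optionally merged into one combined entry at
the reporting stage, which keeps training unambiguous — and Grad-CAM with
the published layer choices (last convolution before global average
pooling for ResBlock; last convolution before the attention blocks for the
Transformer; targets limited to LNM, LVI and tumor size).

## Problem sizes and numerical choices

The original experiments (about 1200 patients, full-resolution mammograms,
25 neural-network slots per architecture) are far beyond a base-R training
loop, so the package's experiments are sized for minutes on one CPU and
these sizes are fixed as the package's study conditions: phantom imaging
cohorts of 90-120 patients at 96 x 64 px with the (8, 16, 32) backbone;
five replicate seeds per direction check; the image stage of the fusion
experiment uses a 2 x 2 nested plan to produce leakage-free mammogram
features while the tabular fusion stage runs the full 5 x 5 plan; the
tabular checks (null-label control, parameter recovery, effect sizes) run
at n = 300-1200. Numerical guards: epsilon-guarded standardization and
normalization (1e-8), BCE probabilities clipped at 1e-7, softmax shifted
by row maxima, early stopping keeps the best-validation-loss snapshot,
and single-image attention requires at least two tokens (self-masked
softmax is undefined otherwise, and errors).

## Known limitations

* Phantom images are geometric caricatures; absolute AUCs on them say
  nothing about clinical performance, and only directions/mechanisms are
  meaningful.
* At desk scale the lesion covers percent-level fractions of a small
  feature map, so global average pooling is close to an ideal lesion-area
  estimator and the ResBlock neck is very strong on tumor-size
  regression; the regime in which attention-based aggregation overtakes
  pooling (tiny lesion fraction in very large maps) is not reachable at
  these image sizes, and the package's neck-comparison experiment
  reflects that honestly (the Transformer does tend to win on the
  halo-driven node-count regression in the same runs).
* The fusion experiment fits clinical z-scoring statistics once on the
  development table rather than per fusion fold; this keeps the
  two variants' comparison paired at desk scale, while full-scale use
  should refit per fold (the encoder supports it).
* MCAR missingness only; the published cohort's missingness mechanism is
  unknown.
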