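---
title: "Methods: a single-shot detector pipeline for stomatal density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a single-shot detector pipeline for stomatal density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Stomatal density (SD, stomata per mm² of leaf surface) is a structural
determinant of a leaf's potential gas-exchange rate and a target trait in
crop phenotyping. The standard assay images an impression (replica) of
the leaf epidermis under a light microscope and counts stomata by eye —
accurate but slow, which caps the panel sizes a breeding program can
phenotype. `stomadet` automates the counting step with a single-shot
multibox detector and wraps it in the full measurement protocol: model
selection against manual counts, count-to-density conversion, positional
aggregation within a leaflet, and panel-level diversity statistics.

A replica micrograph is a hard target for classical blob detection
because the epidermal pavement cells form a rugose relief whose local
contrast rivals that of the stoma complexes themselves. A learned
detector that sees both texture and shape is the appropriate tool.

## The detector

The detector follows the single-shot multibox design: a convolutional
backbone produces one or more spatial feature maps; every cell of each
map carries a small set of *prior boxes* (reference boxes of fixed scale
and aspect ratio); for every prior the network predicts two class logits
(background / stoma) and four offsets that deform the prior into a
predicted box. Offsets use the standard center-size parameterization

    t = ( (cx_g − cx_p)/(w_p v_c),  (cy_g − cy_p)/(h_p v_c),
          log(w_g/w_p)/v_s,         log(h_g/h_p)/v_s )

with variances `(v_c, v_s) = (0.1, 0.2)`. `encode_boxes()` and
`decode_boxes()` are exact inverses (tested to 1e−9).

**Backbone.** The package trains a desk-scale backbone: four 3×3
stride-2 convolutions (8, 16, 32, 64 channels, ReLU) over the 300×300
grayscale input, with linear 3×3 detection heads on the 38×38 and 19×19
maps. At three aspect ratios {1, 2, ½} and scales 0.03 and 0.05 of the
image side this yields 5 415 priors — scales chosen to bracket the
7–11 px boxes that 20–30 µm stoma complexes occupy at the detector
resolution. A deeper VGG-style backbone is configurable through
`ssd_config()`, but the small net is what the tests and benchmarks use:
it is trainable from scratch in minutes on one CPU and is sufficient for
the structured texture of replica imagery. Convolutions are implemented
as im2col (C++) plus BLAS matrix products with hand-derived gradients;
optimization is Adam. All randomness (weight initialization, shuffling)
flows through R's RNG, so a seed pins the entire trajectory.

**Matching and loss.** Each annotated stoma is force-matched to its
best-IoU prior (so no ground truth goes unsupervised even when every
overlap is below threshold), and any prior with IoU ≥ 0.5 to some ground
truth is additionally positive. The training objective is the multibox
loss `(L_conf + α·L_loc)/N`: smooth-L1 on the positive priors' offsets
plus softmax cross-entropy on positives and the hardest negatives, mined
at 3 negatives per positive; `α = 1`, `N` = number of positives. With no
positives the loss is defined as 0. Head class biases are initialized so
the untrained net predicts background nearly everywhere, which keeps the
mined loss finite from the first step.

**Inference.** Decode → keep candidates with stoma probability strictly
greater than the confidence threshold `C_st` → greedy non-maximum
suppression at IoU 0.45, top-200. Degenerate decoded boxes (non-positive
extent after clipping to the image) are discarded before NMS. Because a
box's survival under greedy NMS depends only on higher-scoring boxes —
all of which survive any threshold the box itself survives — filtering
then suppressing at `C_st` equals suppressing once and filtering at
`C_st`. Detection sets are therefore exactly nested along the threshold
axis, and the threshold sweep can reuse one detection pass per image.

## Model selection

The calibration procedure treats the training-set size and `C_st` as the
two free knobs of the measurement instrument. `train_detector()` fits one
model per requested size (50 epochs each — the protocol's fixed training
length); `grid_evaluate()` measures automatic SD on a held-out test set
at every `C_st` from 0.10 to 0.95 in steps of 0.05 and scores each cell
by R² (squared Pearson correlation of manual vs automatic SD — with an
intercept this equals the OLS coefficient of determination) and RMSE.
`select_optimum()` combines the two criteria: cells whose R² sits within
a small tolerance (default 0.01) of the grid maximum are treated as an
R² plateau — the differences are smaller than the batch-to-batch
variability of R² itself — and the plateau cell with the lowest RMSE is
selected. A pure R² argmax (`r2_tol = 0`) is available, but on a flat
ridge it can land on a cell whose counts carry a uniform bias: such a
bias inflates RMSE while leaving the correlation almost untouched, so
RMSE must take part in the decision. `batch_resample_evaluate()` repeats the scoring over
resampled batches (default 10 batches of 50 images) and applies a
Tukey-Kramer all-pairs comparison to the per-batch metrics, which is how
one decides whether two training sizes differ meaningfully. Whether
batches partition the pool or are drawn independently is a flag
(`disjoint`), defaulting to independent draws.

`fine_tune()` continues training from a basal model's weights on a small
annotated set from a new imaging domain (different growth stage,
acquisition protocol, or replica quality), at a quarter of the
from-scratch learning rate.

## The synthetic replica generator

No public annotated stomata dataset accompanies the protocol, so the
package carries a generator (`generate_scene()`, `generate_dataset()`)
that emulates what matters about replica micrographs for detection:

* **Geometry.** The default field of view reproduces a 1840×1840 px
  micrograph at 0.5 µm/px (0.846 mm²) rendered at the 300 px detector
  resolution (3.07 µm/px). Calibration is an explicit parameter
  everywhere because magnification alone does not fix the imaged area.
* **Stomata.** Dark elliptical complexes (two guard cells flanking a
  lighter pore slit), 20–30 µm long × 10–15 µm wide, uniformly rotated —
  order-of-magnitude soybean values, configurable, not biological
  claims. Boxes are the exact axis-aligned bounds of each rendered
  complex.
* **Placement.** Hard-core sampling with a 30 µm minimum center spacing
  (200 retries, then an explicit error): stomata obey one-cell spacing
  and do not overlap. Whether real patterns are clustered or regular is
  not asserted; the count model (`poisson` or `fixed`) and spacing are
  exposed instead.
* **Background.** A two-octave smoothed Gaussian relief field
  (correlation length 20 µm, amplitude 0.08 gray units) mimicking
  pavement-cell ruggedness, plus additive sensor noise (σ = 0.02), 8-bit
  grayscale range.
* **Densities.** Dataset-level densities are drawn uniformly over
  93–166 mm⁻², the span reported across a diverse soybean panel, so the
  regression between true and automatic SD is exercised over a realistic
  dynamic range.

What the generator does *not* emulate: replica artifacts (bubbles,
tears, smears), uneven illumination, out-of-focus blur, and touching or
partially occluded stomata. Tests passing on synthetic scenes therefore
demonstrate that the pipeline's machinery is correct and that the
detector can be trained end-to-end to recover programmed densities; they
do not certify accuracy on any particular real-world imagery, for which
fine-tuning on annotated domain images is the supported route.

The "field-like" shifted domain used in the fine-tuning experiments
(larger 26–36 µm, fainter complexes on rougher, darker relief) encodes
the qualitative report that later-growth-stage field leaves differ in
stoma size, shape and epidermal texture.

## Density aggregation

`stomatal_density()` is count / imaged area (mm⁻²), exact and linear in
the count. The protocol's two-stage averaging is kept explicit: three
micrographs per replica position average into `SD_base`, `SD_middle`,
`SD_tip` (`position_density()`), and `SD_all` is the unweighted mean of
the three positional means (`leaflet_summary()`), *not* the mean of all
nine images — the distinction matters under unbalanced image counts.
Missing images within a position reduce `n_images`; a missing whole
position is an error, never imputed, because the factorial ANOVA needs
complete cells. `accession_summary()` reports per-accession means with
standard errors (sd/√n; undefined at n = 1) plus panel-wide
min/max/mean rows.

## Diversity statistics

* `two_way_anova()`: accession × position factorial with interaction on
  replicate-level records. With the protocol's unbalanced 3–4 leaflets
  per accession, Type II sums of squares are the default (Type I is a
  flag); on balanced data the two coincide, which the tests verify
  against a brute-force mean decomposition. Replicate-level (not
  accession-mean) records feed the model because the interaction term
  needs within-cell replication. Significance is starred at p < 0.01.
* `one_way_anova()`: leaf-area variation among accessions.
* `correlation_sd_la()`: Pearson R with the exact t test.
* `tukey_groups()`: Tukey-Kramer all-pairs comparison using the
  studentized range with the Kramer unequal-n standard error; q
  statistics are computed directly and `ptukey()` supplies adjusted
  p-values. Singleton groups are excluded with a warning.
* `origin_histogram()`: shared-bin stacked counts by origin group,
  default bin width 5 mm⁻².

The two-way ANOVA operates on leaflet-level observations by default;
image-level records can be passed instead by skipping the positional
averaging, a deliberate user choice rather than a hidden switch.

## Numerical and design choices

* **Coordinates** are 0-based half-open pixel intervals internally, so
  integer boxes have exact integer areas; VOC XML is written/read as
  1-based inclusive corners (the LabelImg convention) with conversion
  only at the file boundary.
* **Resize** is bilinear for rasters; box corners scale per axis and
  round half-up (banker's rounding would make scaling
  direction-dependent). Sub-pixel boxes that would collapse are widened
  to one pixel.
* **Training defaults**: Adam at 2e-3 (5e-4 for fine-tuning), batch 8,
  50 epochs, He initialization; chosen on pilot runs of the synthetic
  training task for stable convergence within the protocol's 50-epoch
  budget. An epoch is one full pass over the training subset.
* **Hyperparameters the protocol leaves open** (matching threshold 0.5,
  NMS IoU 0.45, top-k 200, variances 0.1/0.2, 3:1 negative mining,
  α = 1) take the canonical single-shot-detector values; none is claimed
  to replicate the original study's trained model.
* **Problem sizes.** The packaged experiments train on 175 scenes for 50
  epochs and evaluate on 150 held-out scenes (the protocol's optimum
  operating point and test-set size); fine-tuning uses 45 + 40 scenes
  (the field experiment's sizes); the benchmark panel uses 10 pseudo
  accessions × 3 leaflets × 3 positions × 3 images. Unit tests use a
  120 px field of view with the same calibration for speed.
* **Checkpoints** are JSON (weights + full architecture/prior sidecar):
  text, portable, diffable.

## Known limitations

* Single-class detection only (stoma vs background); no multi-class
  extension, GUI, or GPU path.
* The detector's absolute accuracy on real replica imagery depends on
  annotation quality and domain match; the package's measured accuracies
  are on synthetic scenes.
* Leaf area is an external input (cm²); the package does not measure it
  from scanner images.
* Very high densities combined with large minimum spacing can make
  hard-core placement infeasible; the generator fails loudly rather than
  silently relaxing the constraint.
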