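# stomadet

High-throughput stomatal density phenotyping with a single-shot multibox
detector, in R.

## The problem

Stomatal density (SD) — the number of stomata per mm² of leaf surface —
is a structural determinant of a leaf's potential stomatal conductance
and a breeding target for photosynthetic improvement. The standard assay
images a replica of the leaf epidermis under a light microscope and
counts stomata by hand, which caps how many genotypes a program can
phenotype. `stomadet` automates the counting step with a learned object
detector and implements the full measurement protocol around it, for
plant phenomics researchers who need SD at germplasm-panel scale.

## What is inside

* **Detector** (`train_detector()`, `detect()`, `count_stomata()`): a
  single-shot multibox detector over a desk-scale convolutional backbone
  (implemented in the package: im2col/BLAS convolutions, hand-derived
  gradients, Adam). Every cell of two feature maps carries prior boxes
  at scales matched to stoma size; the network regresses center-size
  offsets

      t = ((cx_g−cx_p)/(w_p v_c), (cy_g−cy_p)/(h_p v_c),
           log(w_g/w_p)/v_s, log(h_g/h_p)/v_s)

  and class probabilities, trained with the multibox loss
  `(L_conf + α·L_loc)/N` (smooth-L1 localization + softmax cross-entropy
  with 3:1 hard-negative mining). Inference keeps detections with
  probability strictly above a confidence threshold `C_st` and applies
  greedy non-maximum suppression.
* **Model selection** (`grid_evaluate()`, `select_optimum()`,
  `batch_resample_evaluate()`): sweeps training-set size and `C_st`
  (0.10–0.95 in 0.05 steps), scores each cell by R² and RMSE of automatic
  vs manual SD, and compares models by Tukey-Kramer over resampled
  batches.
* **Fine-tuning** (`fine_tune()`): continues a basal model on a small
  annotated set from a new imaging domain.
* **Density aggregation** (`stomatal_density()`, `position_density()`,
  `leaflet_summary()`, `accession_summary()`): count → mm⁻² via an
  explicit calibration, then the two-stage averaging (three images per
  position; `SD_all` = mean of `SD_base`, `SD_middle`, `SD_tip`).
* **Diversity statistics** (`two_way_anova()`, `one_way_anova()`,
  `correlation_sd_la()`, `tukey_groups()`, `origin_histogram()`):
  accession × position factorial ANOVA (Type II for unbalanced panels),
  SD–leaf-area Pearson correlation, Tukey-Kramer origin-group
  comparison, origin-stacked histograms.
* **Synthetic replica generator** (`generate_scene()`,
  `generate_dataset()`): renders micrograph-like scenes — dark
  guard-cell ellipse pairs with a pore slit on rugose epidermal relief —
  with exact ground-truth boxes, so the whole pipeline is trainable and
  testable without proprietary imagery.
* **I/O**: Pascal-VOC XML annotations (LabelImg dialect), PNG/TIFF
  rasters, CSV manifests, JSON model checkpoints; a CLI at
  `exec/stomadet` with `synthesize / train / finetune / detect / grid /
  benchmark` subcommands.

## Worked example

Train on 175 synthetic annotated scenes (the protocol's optimum training
size), calibrate the confidence threshold on 150 held-out scenes, and
quantify:

```r
library(stomadet)

spec  <- scene_spec()                      # 300 px, 0.846 mm^2 field of view
train <- generate_scenes(175, density_range = c(93, 166), spec = spec, seed = 101)
model <- train_detector(train, epochs = 50, seed = 1)
print(model)
#> Single-shot stomata detector
#>   input 300x300 px, 5415 priors, 4 backbone layers
#>   trained on 175 image(s) for 50 epoch(s), seed 1
#>   final training loss 3.0894

test   <- generate_scenes(150, density_range = c(93, 166), spec = spec, seed = 102)
manual <- sapply(test, function(s) s$truth$sd)   # stands in for manual counts
cal    <- calibration_spec(um_per_px = spec$um_per_px, width_px = spec$image_size)

grid <- grid_evaluate(model, c_st_axis(), test, manual, cal)
print(grid)
#> Evaluation grid: 1 size(s) x 18 threshold(s)
#>   optimum: size 175, C_st 0.20 (R2 = 0.972, RMSE = 5.02)

best <- select_optimum(grid)
auto <- measure_sd(test[1:6], model, best$c_st, cal)
round(rbind(true_sd = manual[1:6], auto_sd = auto), 1)
#>          [,1] [,2]  [,3]  [,4]  [,5]  [,6]
#> true_sd 133.5 92.2 121.7 167.8 109.9 104.0
#> auto_sd 128.8 93.3 128.8 165.4  94.5 105.2
```

Reading the output: the selected operating point (`C_st = 0.20`) gives
R² = 0.972 between true and automatic SD over the 150 held-out scenes
with an RMSE of 5.02 mm⁻² — about 4% of the mean density, i.e. the
automated counts track the truth to within a few stomata per field of
view. The last table shows per-scene density pairs (mm⁻²) at that
operating point. This run takes roughly 10 minutes on one CPU.

Downstream, `quantify_panel()` / `run_benchmark()` apply a fitted model
to a multi-accession panel and run the aggregation and statistics in one
seeded, fully reproducible pass (see the methods vignette).

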