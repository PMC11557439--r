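---
title: "Methods: a cascaded hemorrhage analysis pipeline for TBI CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cascaded hemorrhage analysis pipeline for TBI CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`hemocascade` implements an end-to-end analysis chain for intracranial
hemorrhage (ICH) on axial head CT in traumatic brain injury (TBI):

1. a **slice-level binary filter** that discards hemorrhage-free slices so
   the expensive stages never see them;
2. a **two-stage coarse-to-fine segmenter**: Stage I segments the full
   slice, its binarized output defines a square region of interest (ROI),
   and Stage II re-segments the margin-expanded crop at full resolution;
   the two probability maps are fused by voting;
3. a **mask-guided multi-label subtype classifier** that scores the five
   ICH subtypes (EDH, IPH, IVH, SAH, SDH) from a global view (full slice +
   predicted mask as a second channel) and a local view (ROI crop of both),
   fused at the pooled-feature level;
4. **volumetry**: foreground voxels times voxel volume, in mL;
5. **14-day mortality models** that extend the CRASH clinical predictors
   with the automatically extracted hematoma volume and subtype indicators.

Everything is exercisable on synthetic phantoms; no external imaging data
or pretrained weights are required.

## ROI geometry

All coordinates are row-major, 0-based, half-open. Given a binary mask,
`compute_roi()`:

1. takes the tight bounding box of all foreground pixels;
2. expands the short axis to a square of side `max(height, width)`,
   centered, with any odd leftover pixel assigned to the high-index side
   (a deterministic, documented tie-break);
3. grows the square by a `margin` (default 20 px) on every side — the
   tissue surrounding a hemorrhage carries intensity context that helps
   the fine segmenter, so the crop deliberately includes it;
4. clamps to the image bounds.

Near a border the clamped box can be rectangular. We keep the clamped
rectangle rather than shifting the window — shifting would decenter the
lesion — and `backproject()` uses the actual clamped extent, so the
crop/back-project round trip is well defined everywhere. Both pre- and
post-clamp extents are recorded on the `roi_box` and serialize to JSON for
provenance.

Intensity crops are resampled bilinearly, masks with nearest-neighbour
(labels are never blended), via EBImage.

## Training stack

No deep-learning framework is available to this package at runtime, so the
trainable components are small networks built on in-package RcppArmadillo
primitives (3x3 convolution via im2col + BLAS, 2x2 max pooling, nearest
upsampling) with hand-derived backprop. The test suite validates every
gradient against finite differences.

* **Segmenter (`encoder = "tiny"`)**: a 3-level UNet (channel widths
  `f, 2f, 4f`, default `f = 8`) with skip connections and a 1x1 sigmoid
  output head, trained with soft Dice loss
  `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)`. The smoothing
  `eps = 1` keeps empty-mask samples finite and stable.
* **Classifier backbone**: three conv/pool blocks ending in global average
  pooling (GAP). The binary filter puts a single logistic unit on top; the
  subtype model runs one backbone per view, concatenates the pooled
  vectors and maps them by one linear layer to five sigmoid outputs,
  trained with focal loss (`gamma = 2`, `alpha = 0.25` defaults).

Two numerical choices matter at this scale and are worth stating:

* **Frozen feature standardization.** Raw GAP features of a tiny randomly
  initialized backbone are well separated between classes but numerically
  tiny (~1e-2), which leaves the logistic head near 0.5 for hundreds of
  steps. Each classifier therefore standardizes its pooled vector with
  per-feature mean/sd computed once over the training set at
  initialization and frozen into the checkpoint. Per-sample layer
  normalization was rejected: normalizing within a sample removes exactly
  the between-sample signal the head needs (we measured chance-level
  training when using it).
* **Gradient clipping.** Per-batch gradients are rescaled to a global L2
  norm of at most 1 (`grad_clip`). Without it a single loss spike
  mid-training can saturate every sigmoid in a net this small, a state the
  Dice gradient cannot escape; with clipping the loss curves are smooth
  across seeds.
* **Discriminative learning rates.** Adam's per-parameter step is roughly
  `lr` regardless of gradient scale; at `lr` large enough for the head to
  converge in a few hundred steps, the convolutional weights (He-init sd
  ~0.15) would be scrambled. The head therefore trains at
  `lr * head_lr_mult` (default 10) while the backbone moves slowly.

The optimizer is Adam under a cosine-annealed schedule throughout, which
follows the published full-scale recipe; that recipe's initial rate
(`1e-4`, 500 epochs) remains the configuration default and is what a
full-scale `resnet50`/`efficientnet_b6` run would use. The desk-scale
presets used by the experiments and tests run `lr = 1e-3` for 12-30
epochs, the regime in which the tiny backbones actually converge.
`resnet50`/`efficientnet_b6` encoders and the `deeplabv3plus` head are
accepted in configurations but raise an error when selected: they require
pretrained weights that are not bundled.

Training is bit-reproducible under a fixed seed on one thread: all
randomness (init, shuffling, augmentation) flows from the config seed, and
checkpoints (`save_model()`/`load_model()`) reproduce predictions exactly.

## Augmentation

`augment()` applies, each with probability 0.5: horizontal flip, vertical
flip, rotation within ±45°, zoom 80-120%, translation within ±20% of the
side, and shear 0-10%. Image and mask receive the identical transform;
masks are warped with nearest-neighbour. Flips are exact array reversals
(so a double flip is the identity); the remaining transforms compose into
one affine warp about the image center.

## Vote fusion

The published mechanism for combining Stage I and Stage II predictions is
described only in supplementary material that is not available, so the
default here is the symmetric choice: pixel-wise **mean** of the two
probability maps, thresholded at 0.5. It reduces to either voter when they
agree, and `union` / `intersection` strategies are provided for
sensitivity analysis. Stage II is trained on ground-truth ROIs (as the
source work states) and applied at inference to Stage-I-derived ROIs; when
Stage I finds nothing the slice is returned empty and Stage II never runs.

## Synthetic phantoms

`generate_phantom_series()` draws stylized axial slices: a bright
elliptical skull ring, mid-gray parenchyma (0.35), a darker central
ventricle (0.15), and 0-3 lesions per slice whose geometry encodes the
subtype:

| subtype | geometry |
|---|---|
| EDH | biconvex lens abutting the inner skull (intersection of two discs) |
| SDH | thin crescent hugging the inner skull |
| IPH | compact elliptical blob inside the parenchyma |
| IVH | blob confined to the ventricle |
| SAH | thin curvilinear arcs at mid radii |

Lesions are brighter than parenchyma by `lesion_intensity_contrast`
(default 0.35) *before* Gaussian noise (default sd 0.03), so ground-truth
masks are pixel-exact by construction. The EDH lens is sized analytically
(two discs of radius `r` at distance `r` intersect in area `~1.228 r^2`)
so the mean lesion area tracks the configured `lesion_area_px`; arcs solve
their angular width from the band's pixel count. These geometries are
deliberately stylized priors: subtype is inferable from shape and
position, which is precisely the signal the fusion classifier needs. They
do not emulate Hounsfield-accurate tissue, partial-volume effects, beam
hardening, motion artifacts, or anatomical variability — so passing tests
demonstrate that the pipeline machinery works and that its comparative
claims (cascade ≥ single stage, fusion ≥ global-only) hold when the signal
exists, not that clinical-grade accuracy would be reached on real CT.

Defaults mirror the test conditions used throughout: 64 px slices (512 is
supported; spacing defaults scale so the head's physical size is
constant), half of the slices empty, target lesion area 1.5% of the slice
area.

## Synthetic cohorts

`generate_cohort()` draws moderate-to-severe TBI patients: age from a
truncated normal (18-80 years, median near 57.5), GCS from 3-12, CT and
clinical findings as Bernoulli draws, hematoma volume lognormal
(median 15 mL), and subtype indicators. Two outcomes are generated from
stated logistic models over the full CRASH-CT + volume + subtype design:
`death14` (scheme A) and `death_or_coma14` (scheme B, a higher base rate
with a stronger GCS effect). The true per-row linear predictors are stored
so that coefficient recovery is a checkable oracle. The default
coefficient preset gives roughly 30% scheme-A mortality, matching the
scale of a moderate-to-severe TBI cohort.

Age enters the linear predictor on the standardized Box-Cox scale, and the
generator and `build_features()` share one code path for the design
matrix; this makes the "fit recovers the truth" property exact rather than
approximate, at the price that the age coefficient is per-SD of
transformed age rather than per-year.

## Outcome models

`build_features()` produces the nested design matrices:
`CRASH_BASIC` (standardized Box-Cox age, GCS, two pupil dummies with
both-reactive as reference, major extracranial injury) ⊂ `CRASH_CT`
(+ petechiae, effaced basal cistern, traumatic SAH, midline shift,
nonevacuated hematoma) ⊂ `CRASH_CT_VOL` (+ volume in mL) ⊂
`CRASH_CT_VOL_SUB` (+ five subtype indicators).

`box_cox()` picks its exponent by profile maximum likelihood on the grid
[-3, 3] step 0.01 (the estimate matches `MASS::boxcox` to grid
resolution; that package is used only as a test oracle). The transform is
fitted on the full cohort before cross-validation — a small, documented
leakage accepted for simplicity, as the transform depends only on the
marginal age distribution, not the outcome. `box_tidwell()` augments the
logistic model with `x*log(x)` and returns that term's Wald p-value; its
Monte-Carlo calibration (type-I error near the nominal 5% at n = 2000,
high power against log-shaped effects) is measured by the acceptance
experiments rather than asserted.

`fit_predict_cv()` runs stratified 5-fold cross-validation (stratified
rather than plain, so ~150-patient cohorts cannot produce single-class
folds) for logistic regression or a 500-tree random forest (`sqrt(p)`
features per split, unlimited depth — standard defaults, configurable),
scoring accuracy/precision/recall/F1 at threshold 0.5 plus out-of-fold ROC
AUC. `feature_importance()` averages the forest's mean decrease in
impurity across folds and normalizes shares to 1.

## Metrics

Dice = `2|A∩B| / (|A| + |B|)`, IoU = `|A∩B| / |A∪B|`; a pair of empty
masks scores 1.0 (predicting "no hemorrhage" on a clean slice is
correct). Micro-averaged classification metrics pool the `5n` per-label
decisions; both subset accuracy and per-label mean accuracy are reported
under distinct names since "accuracy" alone is ambiguous for multi-label
output. Per-subtype segmentation scores attribute a slice's binary-mask
score to every subtype present in its reference labels.

## Experiment scales

The packaged experiments (`run_*_experiment()`, also used by
`scripts/acceptance.R`) run at phantom scale, chosen so each completes in
minutes on one CPU while leaving the comparative claims testable:

* filter: 200 training slices (half empty), 20 epochs, 60 held out;
* cascade: 200 training slices, 30 epochs per stage, 50 held-out
  lesion-bearing slices, paired bootstrap (2000 resamples) on the Dice
  difference;
* fusion: 300 training inputs, 12 epochs, 3 seeds, 60 held out, against
  the global-only ablation on identical data and seeds;
* outcome models: 2000-patient cohorts; coefficient-recovery coverage over
  20 cohorts of 5000;
* Box-Tidwell calibration: 200 replicates of n = 2000 per scenario.

## Known limitations

* The tiny backbones are far below clinical capacity; absolute Dice /
  accuracy on real CT would require the full-scale encoders and external
  training data, which are out of scope here.
* Binary segmentation with classifier-carried subtype semantics: the
  segmenter does not emit subtype-coded masks (a multi-class mask mode
  exists in the data model via `label_mask(encoding = "subtype")`, but the
  trained path is binary).
* The vote rule is a stand-in for an unpublished mechanism (see above).
* Phantom realism limits, and the Box-Cox leakage note, as discussed.
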