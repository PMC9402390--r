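---
title: "Methods: multi-view ensemble segmentation of resection cavities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view ensemble segmentation of resection cavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After epilepsy surgery (anterior temporal lobectomy, selective
amygdalohippocampectomy, or laser ablation), the resected tissue leaves a
CSF-filled cavity that appears hypointense on postoperative T1-weighted MRI.
Quantifying that cavity -- its volume, and which anatomical regions it
removed -- matters for predicting surgical outcome (hippocampal remnant
volume in particular), but manual segmentation is slow and rater-dependent.
`resectr` implements a fully automated pipeline: a 2.5D ensemble of 2D
segmentation networks, one per anatomical plane, fused per voxel and cleaned
by connected-component analysis, followed by atlas-intersection remnant
volumetry.

## The model

### Geometry and preprocessing

All volumes are first reoriented to a fixed right-handed RAS frame
(`canonicalize()`), against which plane names are defined: *axial* slices
along the third (inferior-superior) axis, *coronal* along the second,
*sagittal* along the first. The affine is updated during reorientation, so
every voxel keeps its world coordinates; the operation is idempotent and a
pure re-indexing.

Each 3D volume is min-max normalized as a whole to [0, 1]
(`normalize_intensity()`); per-volume rather than per-slice normalization
keeps relative slice brightness intact. Slices are then centre-padded with
zeros to a square -- padding, not anisotropic stretching, preserves the
aspect ratio of anatomy -- and resampled bilinearly to the network
resolution (`extract_slices()`). The per-slice transform log makes the
mapping invertible: predictions are inverse-resized, inverse-padded, stacked
along the slicing axis and thresholded at 0.5 (`reassemble()`). For binary
masks at native resolution the round trip is exact; across a resize it is
interpolation-limited (the test suite demonstrates Dice >= 0.95 on phantom
masks). Masks and predictions are resized with linear interpolation and
re-thresholded at 0.5, which avoids staircase artifacts while keeping masks
binary. Empty (all-background) slices are retained in training data: the
network must learn to emit empty masks on cavity-free slices, which is what
makes control screening possible downstream.

### The per-plane segmenter

Each plane has an independent 2D encoder-decoder network (a compact U-Net):
`encoder_depth` resolution levels of two 3x3 convolutions + ReLU followed by
2x2 max pooling, a two-convolution bottleneck, and a mirrored decoder with
nearest-neighbour upsampling and skip concatenations, closed by a 1x1
convolution and sigmoid. The encoder is a from-scratch, depth- and
width-configurable convolutional stack; pretrained encoder weights are
deliberately not bundled (the `pretrained_encoder` flag exists as contract
and refuses `TRUE`), keeping every result reproducible offline from a seed.

The loss is batch-global soft Dice (smoothing constant 1). The field's
training protocols for this task select models by validation Dice, so a
Dice-aligned loss is the natural choice; it also behaves sensibly on empty
slices, where it simply pushes total predicted mass down. Optimization is
Adam (beta1 0.9, beta2 0.999). The returned parameter state is the one
maximizing validation DSC over epochs, matching the validation-DSC model
selection objective; training history (per-epoch loss and validation DSC)
is stored on the model.

Default protocol settings mirror standard clinical training for this task:
50 epochs, learning rate 1e-4, batch size 16, augmentation by random
horizontal/vertical flips, rotations up to 10 degrees, and shifts up to 10%
of width/height. Augmentation applies the identical geometric transform to
image and mask (bilinear for the image, nearest-neighbour for the mask,
zero fill out of bounds). All randomness -- splits, initialization,
augmentation, batching -- flows from one config seed; weight initialization
uses a self-contained Box-Muller generator over a seeded mt19937 stream so
results do not depend on standard-library distribution implementations.

### Cross-validation protocol

`make_folds()` produces subject-level k-fold splits: subjects are shuffled
once, partitioned into k groups; fold i tests on group i, validates on the
next group cyclically, and trains on the rest -- a 3:1:1 split at k = 5,
with every subject held out for testing exactly once. All slices of a
subject stay in one set; an assertion makes subject-level leakage
impossible by construction.

### Ensemble fusion and post-processing

The three reassembled plane masks are fused per voxel by majority vote: a
voxel is included iff at least `min_votes` (default 2 of 3) plane models
label it. Fusion operates on binarized masks, not averaged probabilities,
because the vote is defined over labels. The fused mask then passes
connected-component filtering: the default `largest` mode keeps the single
largest component (training assumes one contiguous resection site), while
`min_size` keeps all components above a voxel-count threshold for
multi-site surgeries. "Isolated voxels" is deliberately interpreted in both
ways since either reading is defensible. Components use 26-connectivity by
default -- resection cavities are bulky, and 26-connectivity is the more
permissive reading; 6-connectivity is available. Finally a detection screen
empties any prediction below `detection_threshold_ml` (default 0.5 ml,
equal to 500 voxels at 1 mm isotropic; the voxel equivalence holds only at
that spacing, which is why the threshold is expressed in ml). The screen is
what turns small spurious control-scan segmentations into "no detection".

## Evaluation metrics

* **DSC** = 2|X∩Y| / (|X|+|Y|). Both-empty masks score 1 (perfect
  agreement on absence -- needed for control subjects); one-empty scores 0.
* **HD95**: boundary voxels are foreground voxels with at least one
  background 6-neighbour (the volume edge counts as background). Distances
  are between voxel centres in mm using the voxel spacing, so anisotropic
  grids measure correctly. The reported value is the symmetric max of the
  two directed 95th-percentile distances, the variant used by the common
  segmentation challenges; percentiles interpolate linearly (R type 7),
  documented for cross-platform determinism. Undefined (NA with a warning)
  when either mask is empty.
* **Volumes** are foreground counts times the voxel volume; **PVD** =
  |pred − true| / true × 100 with the manual volume as denominator (it is
  an error measure of the prediction), undefined at true volume 0.
* **Detection outcomes**: a resection subject is a false negative iff
  prediction and truth share no voxel at all (an overlap criterion,
  deliberately weaker than DSC); a control subject is a false positive iff
  anything survives screening.
* Cohort summaries report median/IQR/mean/SD for DSC and HD95 (undefined
  HD95 values excluded and counted), Pearson r and MAE between manual and
  predicted volumes, and FN/FP counts. `stratify_by_size()` splits at a
  manual-volume threshold (default 17.92 ml, the conventional small/large
  resection cut) and compares DSC and PVD between groups with two-sample
  t-tests.

## Remnant volumetry

`intersect_parcellation()` intersects an aligned integer label volume with
the resection mask. Per region, `resected + remnant = total` holds exactly
in voxel arithmetic; resection voxels over background label 0 are reported
as *unassigned* rather than dropped, so volume is conserved globally and
auditable. Registration (including cost-function masking of the resection
zone) is out of scope: the module requires pre-aligned inputs and fails
loudly on any geometry mismatch. Both arms of
`compare_remnant_estimates()` are mask-intersection estimates -- there is
no voxel-wise remnant ground truth to compare against -- so the comparison
is exactly manual-mask-derived vs predicted-mask-derived percent resected.

## The phantom generator

Clinical images cannot ship with the package, so every stage is exercised
on synthetic phantoms with analytically known ground truth
(`generate_phantom()`). What it emulates:

* a brain-like ellipsoid with tissue-intensity structure (cortex shell 0.5,
  white-matter interior 0.75, two ventricle analogues 0.25, all pre-noise);
* a hypointense ellipsoidal cavity (intensity 0.08, CSF-like, below every
  tissue band) whose voxel set *is* the ground-truth mask;
* optional failure-mode artifacts mirroring the real error sources: a
  hyperintense inclusion strictly inside the cavity (blood product /
  ablation necrosis) and a thin (~1 voxel radius) surgical tract from the
  cavity to the brain surface, whose voxels join the ground-truth mask as
  a manual rater would include them;
* additive Gaussian noise (sd 0.03), clipped to [0, 1] -- the simplest
  model sufficient to exercise normalization and learning;
* control phantoms with no cavity;
* a toy parcellation of eight octant wedges plus an interior "hippocampus"
  ellipsoid at the cavity site, tiling the brain interior exactly.

What it does **not** emulate: MRI physics (bias fields, gliosis, edema,
partial voluming, brain shift), anatomical realism, or inter-rater
labelling variability. Passing phantom tests therefore demonstrates that
the pipeline's machinery -- preprocessing, training, fusion,
post-processing, metrics, volumetry -- is correct and end-to-end trainable,
not that clinical-grade accuracy transfers to real scans.

Cohorts (`generate_cohort()`) draw cavity radius and centre uniformly from
stated ranges with rejection so the cavity always fits inside the brain,
and derive per-subject seeds from the cohort seed, so a cohort is
bit-reproducible.

## Desk-scale study conditions

`phantom_study()` runs the whole pipeline at sizes chosen for a single CPU:
25 cavity subjects on 64^3 grids at 1 mm isotropic, first fold of the
5-fold 3:1:1 split (15 train / 5 validation / 5 test, i.e. 20 subjects
enter training), 5 control phantoms, network resolution 64, a
depth-2/width-4 network, 10 epochs at learning rate 1e-3 (the higher rate
compensates for the short desk-scale schedule; the package default config
retains the 50-epoch/1e-4 clinical protocol). Cavity radii span 7-14 mm.
These sizes were fixed once as the package's reference conditions and are
what `scripts/acceptance.R` re-runs.

## Numerical choices and degenerate inputs

* Resampling aligns pixel centres so that equal input/output sizes are the
  exact identity; bilinear sampling clamps at edges and fills 0 outside.
* Constant-intensity volumes normalize to all zeros with a warning rather
  than erroring (a defensible reading of a degenerate input).
* Component-size ties in `largest` mode resolve to the first-labelled
  (lowest-index) component, deterministically.
* The cavity-containment check uses the conservative bounding-ball
  criterion ||c/A|| + max(r/A) <= 1 in brain-normalized coordinates.
* Dice smoothing constant 1 in the loss; metric DSC uses the exact formula
  with explicit empty-mask conventions.
* Slice dimensions must be divisible by 2^depth; the network refuses
  otherwise rather than silently cropping.

## Known limitations

* The segmenter is a compact from-scratch network: adequate for phantoms
  and for validating the pipeline, far smaller than what clinical accuracy
  requires.
* Brute-force nearest-boundary search in HD95 is O(n·m) over boundary
  voxels; fine for desk-scale masks, slow for dense clinical meshes.
* No registration: remnant volumetry trusts the caller's alignment.
* The phantom generator's simplifications listed above bound what the
  green test suite can claim about real data.
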