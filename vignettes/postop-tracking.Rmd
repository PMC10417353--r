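---
title: "Post-surgical GTV segmentation and longitudinal BT-RADS tracking: methods"
author: "gliotrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-surgical GTV segmentation and longitudinal BT-RADS tracking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotrack)
```

## The problem

After glioblastoma surgery, radiation treatment planning requires two gross
tumor volumes contoured on MRI: GTV2, the high-dose target covering the
resection cavity and any residual enhancing tumor on contrast-enhanced
T1-weighted imaging (CE-T1w), and GTV1, the lower-dose target covering the
T2w/FLAIR hyperintense region — edema and infiltrative disease — which
contains the cavity and blood products. Post-operative anatomy is what makes
this hard: the cavity is dark on CE-T1w, often abuts the skull, and residual
enhancement can be a thin rim or a small nodule easily confused with
vessels. The same segmentations, tracked over follow-up visits, drive
structured response reporting (BT-RADS) from volumetric percent-change
cutoffs.

`gliotrack` implements this pipeline end to end at desk scale: a synthetic
phantom generator that emulates post-surgical morphology with analytic
ground truth, the preprocessing chain and 3-channel input recipe, a
trainable depth-3 3D U-Net with Dice loss, the evaluation triad
(Dice / Jaccard / directed Hausdorff), multi-level Otsu cavity removal, and
the longitudinal BT-RADS decision engine.

## Synthetic phantoms

No public post-operative GTV dataset exists, so every stage is exercised on
generated phantoms. A `phantom_spec()` places, inside a spherical brain
surrounded by a spherical skull shell:

* a spherical resection **cavity** (dark on CE-T1w, fluid-suppressed on
  FLAIR),
* a thin **enhancing rim** around it, with a mild radial two-tone profile
  (heterogeneous enhancement),
* an optional residual enhancing **nodule** seated just outside the rim,
* a larger **edema** sphere, hyperintense on FLAIR, and
* a **blood-product crescent** just outside the rim (hyperintense on FLAIR);
  it carries no separate mask because it is never scored separately.

Ground truth is `gtv2 = cavity ∪ rim ∪ nodule` and
`gtv1 = edema ∪ gtv2`, so the nesting `GTV2 ⊆ GTV1` holds by construction.
Spheres are used deliberately: every target volume has a closed form
(`analytic_volumes()`), so voxelization accuracy is checkable (within 5% at
the default resolutions). Intensities are arbitrary-unit tissue means
(tissue scale 100) plus Gaussian noise of standard deviation
`noise_sd * 100`; air stays exactly zero so that nonzero-voxel
normalization is well defined. Intensity means are specified **per
modality** — a single class mean cannot express that edema is isointense on
CE-T1w but bright on FLAIR.

The default grid is 64³ voxels at 2 mm isotropic spacing (tests mostly use
48³); full-size (256, 256, 160) volumes are supported but not default. What
the phantoms do *not* emulate: MRI physics (bias fields, k-space
artifacts), irregular lesion shapes, multifocality, or realistic intensity
distributions. Passing tests on phantoms therefore demonstrates that the
machinery is correct — resampling, channel assembly, optimization, Otsu
separation, volumetry, scoring — not that the network would reach any
particular accuracy on patients.

Longitudinal series (`generate_series()`) rescale the lesion analytically:
the edema radius by the cube root of the FLAIR volume multiplier, and the
rim/nodule by a jointly solved scale factor so the enhancing-compartment
volume hits its multiplier exactly; a multiplier of 0 collapses the
enhancing compartment onto the bare cavity.

## Preprocessing

The chain mirrors standard practice: volumes co-registered onto the CE-T1w
grid (registration *estimation* is out of scope; inputs are required
pre-registered), resampled to a common shape — trilinear for images,
nearest-neighbor for masks, with the half-voxel convention so the physical
field of view is preserved and an identity-shape resample is exact — then
zero-mean/unit-variance normalization over the **nonzero** voxels only
(population denominator), leaving background at exactly zero.

The model input is a 3-channel stack whose order encodes the target:

| target | channel 1 | channel 2 | channel 3 |
|---|---|---|---|
| GTV1 | FLAIR, skull-stripped | CE-T1w, skull-stripped | FLAIR, with skull |
| GTV2 | CE-T1w, skull-stripped | FLAIR, skull-stripped | CE-T1w, with skull |

The with-skull channel exists to help delineate cavities that abut the
skull. Each channel is normalized on its own support (the with-skull volume
over the whole head, stripped volumes over brain only) so every channel is
internally standardized. Assembly is a pure selection; no voxel values are
altered.

Training samples are crops (default 128³; the desk-scale tests use 32³ from
48³ phantoms). With probability 0.5 a crop is centered on a uniformly drawn
foreground voxel, otherwise placed uniformly — plain uniform sampling wastes
most crops on background at realistic lesion fractions.

## The 3D U-Net and training

The network is a standard encoder–decoder with three max-pooling levels,
two 3×3×3 convolution + instance-norm + ReLU layers per block, skip
connections by channel concatenation, nearest-neighbor upsampling, and a
1×1×1 sigmoid head giving per-voxel foreground probability. Filters double
per level from `base_filters` (default 32, i.e. 32-64-128 with 256 at the
bottleneck; the desk-scale tests use 8). GTV1 and GTV2 are trained as two
independent binary models with their respective channel recipes. There is
no deep-learning framework dependency: convolutions are im2col + GEMM in
C++/Armadillo with hand-written backpropagation, verified against central
finite differences in the test suite.

Training minimizes the soft Dice loss
\(1 - (2\sum p t + s)/(\sum p + \sum t + s)\) with smoothing
\(s = 10^{-5}\), using Adam (default learning rate 1e-4, exposed in
`train_config()`), on-the-fly augmentation (random axis flip and random
90°-multiple axial rotation, each with probability 0.5, applied identically
to image and label so labels stay exact), reduce-on-plateau learning-rate
scheduling (factor 0.5, patience 5), and early stopping when the mean
validation Dice of thresholded predictions (cutoff 0.5) has not improved
for 10 epochs — ties do not reset the counter. The checkpoint with the best
validation Dice is returned. With one RNG seed in `train_config()` the
whole run (shuffling, crops, augmentation) is reproducible.

Problem sizes in the tests were chosen to make each property observable on
a plain CPU: the overfit-one-phantom check runs a base-4 net on a 32³ case
(converges past Dice 0.9 within 50 epochs at learning rate 1e-2, no
augmentation), and the recovery check trains a base-8 net on 20 phantoms at
48³ with 32³ crops and learning rate 1e-3, reaching mean held-out Dice
above 0.8 within a dozen epochs. The default 1e-4 rate is kept for
realistic-scale runs; the desk-scale runs pass their own `train_config()`.

Inference (`predict_volume()`) runs sliding windows whose probabilities are
blended with a Gaussian center-weighted importance map and thresholded at
0.5. A window equal to the (padded) volume is exactly one forward pass, the
default. Two effects make small-window stitching differ from the whole-pass
result: instance-norm statistics are computed per window, and the zero-pad
halo covers most of a small window at this receptive field (~40 voxels at
depth 3). The center-weighting suppresses but cannot eliminate this, so
windows should be chosen large relative to the receptive field; the test
suite asserts exact identity for whole-volume windows and overlap-level
agreement for stitched ones.

## Evaluation metrics

`dice()` and `jaccard()` are the usual overlap ratios, with the convention
that two empty masks agree perfectly (1.0); they satisfy
\(J = D/(2-D)\), asserted to 1e-9 across random mask pairs. `hausdorff()`
is deliberately the **directed** distance — the largest, over ground-truth
voxels, of the distance to the nearest prediction voxel, in mm between
voxel centers — rather than the more common symmetric HD95: it is zero
whenever the ground truth is covered by the prediction, and it is the
definition used by the evaluation this package mirrors. A `symmetric` flag
exists. Implementation is an exact anisotropic Euclidean distance transform
(three-pass lower-envelope algorithm); the suite checks it against O(n²)
brute force on hundreds of random mask pairs. Empty masks yield `Inf` with
a warning.

## Cavity removal and volumetry

Because GTV2 deliberately includes the dark cavity, longitudinal tracking
of the *enhancing* lesion first removes it: intensities inside the GTV2
mask are clustered into four classes by multi-level Otsu thresholding
(128-bin histogram; an exact dynamic program over cut positions, equivalent
to exhaustive search, maximizes the between-class variance), and exactly
the lowest-intensity class is dropped. The result is always a subset of the
input mask; if the masked intensities cannot support four nonempty classes
the mask is returned unchanged with a warning. Otsu cut positions are
invariant to affine intensity rescaling (up to binning), so running on raw
or normalized CE-T1w is immaterial; the pipeline uses normalized. No
morphological cleanup is applied by default (an optional
largest-connected-component flag exists but is off). FLAIR lesion volume
for tracking is the full GTV1 segmentation volume, uncorrected. Volumes are
voxel count × voxel volume, reported in cc.

## The BT-RADS decision engine

Percent change is referenced to the immediately preceding visit (a
baseline-referenced mode is not provided; the tracked quantity is
visit-over-visit change). Volumes below `min_measurable_cc` (0.1 cc) count
as absent: a lesion appearing from below the floor is a new lesion, one
falling below it is resolved, and two sub-measurable volumes are 0% change.

The per-visit decision tree, in order:

1. baseline visit → **0**;
2. FLAIR volume *changed* by ≥ 100% (either direction in the default mode —
   the literal reading of "changed"; an increase-only switch exists), or
   enhancing volume increased ≥ 40%, or a new measurable lesion → **4**;
3. enhancing ≥ +20% or FLAIR ≥ +50% (all cutoffs inclusive) → **3**, with
   sub-grade **c** if the previous visit was itself worsened below the
   recurrence cutoffs (the consecutive-worsening rule; it takes precedence
   over the post-RT window), **a** if within `post_rt_window_days` (90) of
   radiotherapy completion — "shortly after RT" operationalized as ≤ 90
   days, configurable — else **b** (also the fallback when the RT date is
   missing, with a warning);
4. mixed findings — one measure decreased beyond the ±10% stability band
   while the other increased beyond it → indeterminate **3b**;
5. both measures decreased beyond the band (or resolved) → **1**;
6. otherwise → **2**.

Rule 4 and the ±10% band are this package's operationalization of
"improved or stable versus mixed": the published description does not print
numeric conditions for the indeterminate case, so the band is a stated,
configurable decision. One consequence worth knowing: the major score is
monotone in either percent change only on the region where both changes
are above the improvement band — a FLAIR drop from −30% to −5% at enhancing
+12% moves the code from 3b to 2, because the mixed-findings rule no longer
fires. The property tests assert monotonicity on the region where it
genuinely holds.

Only rule 3 sets the worsened flag that feeds the consecutive-visit 3c
rule, so a 3c can never be the first worsened visit of a series, and a
rule-4 3b breaks the chain. Every result carries the ordered list of fired
rules as its rationale.

## Numerical choices and edge cases

* Normalization requires ≥ 2 nonzero voxels with nonzero variance;
  degenerate volumes raise errors rather than silently passing NaNs.
* Dice-loss smoothing 1e-5; instance-norm epsilon 1e-5; He weight
  initialization; the final bias starts at 0 (an untrained net on zero
  input predicts exactly 0.5 everywhere).
* Rotations are restricted to 90° multiples in the axial plane so labels
  transform exactly; rotation is skipped (flip still applies) if the axial
  plane is non-square.
* Multi-level Otsu forbids empty classes; thresholds are midpoints between
  the last occupied bin of one class and the first occupied bin of the
  next.
* Hausdorff on an empty mask is `Inf` with a warning, never an exception,
  so batch evaluation keeps going.
* The distance transform uses a large finite sentinel (1e30) instead of
  `Inf` internally; the lower-envelope recursion is undefined on infinite
  parabola heights.

## Limitations

Spherical phantoms cannot probe shape-dependent failure modes (ventricle
confusion, infiltrative margins, small satellite lesions). The 4-class
Otsu step assumes the cavity is the lowest-intensity cluster inside GTV2 —
true for the phantom contrast and typical post-operative appearance, but a
hemorrhagic cavity bright on T1 would violate it. The scoring engine
implements only the volumetric arm of BT-RADS; diffusion/perfusion
features, new geographic lesions and medication context are out of scope
(medication metadata passes through untouched). Training at full
(256, 256, 160) resolution is supported by the same code paths but is a
GPU-scale undertaking outside the test suite.
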