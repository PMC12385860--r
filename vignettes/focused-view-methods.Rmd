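---
title: "Focused-view CT urography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focused-view CT urography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(focusctu)
```

## The problem

CT urography (CTU) images the whole abdomen to answer a narrow clinical
question: is there a lesion in the kidneys, ureters or bladder? Everything
else the scan shows — bowel, pancreas, liver, vessels — is a potential
*incidental finding*, detected by chance, with uncertain benefit and
well-documented downstream costs. A *focused view* rendering replaces
every voxel outside the urinary tract with a fill value so that only the
organs of interest remain visible, which both removes visual distraction
and makes a randomized comparison of "full" versus "focused" reading
possible.

`focusctu` implements the image-processing core of that idea for paired
scans (a contrast-enhanced CTU plus its unenhanced companion), together
with the scaffolding needed to study it without clinical data: a
synthetic phantom generator with analytic ground truth, a compact
trainable 3-D U-Net segmenter, rigid/affine registration, and
reader-study style evaluation statistics.

## Masking methods

Given a `label_volume` with classes background/kidney/ureter/bladder,
three masks of increasing permissiveness are defined:

* **Method 1** — the raw segmentation: a voxel is visible iff its label
  is nonzero.
* **Method 2** — method 1 dilated by a spherical structuring element of
  radius `boundary_mm` (default **10 mm**). The radius is specified in
  physical millimetres: on anisotropic grids the element is ellipsoidal
  in index space. The boundary exists so the *outer edges* of organs —
  exactly where wall lesions sit — survive imperfect segmentation.
  Dilation is computed through an exact anisotropic Euclidean distance
  transform, so it agrees voxel-for-voxel with brute-force distance
  thresholding.
* **Method 3** — method 2 plus *bridging*: connected-component analysis
  is run on the union of tract labels; while more than one component
  remains, a disconnected component containing ureter voxels (tie-break:
  smallest, then lowest lexicographic centroid) is joined to its nearest
  other component by a straight rasterized voxel path between their
  closest surface voxels (Euclidean mm). Each path is dilated by
  `bridge_radius_mm` (default **20 mm**) and unioned with the method-2
  mask. Bridging guarantees a connection between both kidneys and the
  bladder even when parts of a ureter were never opacified and therefore
  never segmented.

Design points that the task description left open, decided here:

* *Straight path endpoints*: the closest pair of surface voxel centres,
  not centroids — centroids of curved components can lie outside them.
* *Radii do not stack*: bridge paths are dilated by `bridge_radius_mm`
  alone and unioned with the boundary mask; a path is not additionally
  thickened by the 10 mm boundary.
* *Connectivity*: 26-neighbour by default (most permissive standard
  choice, fewest spurious gaps); configurable.
* *Fill value*: −1024 HU (air), unambiguous in any CT viewer.
* *Bridging order*: any ureter-bearing component may connect to any
  nearest component (including another fragment) — the kidney–bladder
  connection is asserted on the final result, not forced stepwise.

Masking itself is `apply_mask()`: voxels inside the mask are copied
bit-exactly, voxels outside become the fill value; the operation is
idempotent. Method 1 ⊆ 2 ⊆ 3 holds by construction and is asserted
property-style in the test suite.

## Registration

The unenhanced scan is acquired minutes before the CTU and the patient
moves; the mask (computed in the CTU frame) can only be applied to the
unenhanced volume after alignment. `register()` maximizes the Pearson
cross-correlation between the fixed volume and the pulled-back moving
volume over a 3-level coarse-to-fine pyramid, with quasi-Newton updates
on scaled parameters (1 unit ≈ 1 mm displacement at the volume centre;
finite-difference step 0.1 units). Both model classes are available:
a full 12-parameter affine and a 6-parameter rigid restriction.
`focused_view()` defaults to **rigid**, which is the restriction the
pipeline needs (patient motion between two same-session supine
acquisitions is rigid to good approximation) and is markedly better
conditioned: in phantom experiments the affine model's extra degrees of
freedom absorb metric noise and leave ~2° rotation errors, while the
rigid model recovers misalignments up to 10 mm / 10° to within 0.5 mm
and 0.1°.

Two numerical choices matter and are easy to get wrong:

* **Fixed metric region.** The correlation is evaluated on a fixed
  interior region of the fixed grid (inset `margin_mm`, default 20 mm),
  *not* on the varying in-field overlap. If the sample set changes with
  the transform, the metric is discontinuous at every voxel-crossing —
  including a spike at the identity — and line searches fail there.
  Out-of-field samples take the air value.
* **Pre-smoothing.** One (1,2,1)/4 separable smoothing pass (plus one
  per pyramid halving, as antialiasing) is applied to both volumes
  before metric evaluation. Interpolation of the moving image smooths
  its noise; without equalizing smoothing the optimizer is rewarded for
  *mis*aligning by fractions of a voxel.

The optimizer stops per level when the relative metric improvement drops
below `tol` (1e-8) or the level's iteration cap is reached (100/40/15
coarse-to-fine by default). The returned transform carries the final
metric, the metric at identity, and the evaluation count.

## The phantom

`generate_phantom()` renders an analytic abdomen onto the voxel grid: a
voxel gets a label iff its centre lies inside the shape, with precedence
kidney > bladder > ureter where shapes meet (ureters deliberately start
inside a kidney and end inside the bladder so the gap-free tract is one
connected component).

* **Kidneys and bladder** are ellipsoids; their voxelized volumes match
  4/3·π·abc within the voxelization error bound tested at small-grid
  resolution (10%).
* **Ureters** are tubes of radius `ureter_radius_mm` around a polyline
  centreline: the tube is the exact set of points within the radius of
  the polyline, and each voxel's arc-length position is the projection
  onto the polyline. A *gap* removes the observed (but never the truth)
  ureter label on an arc interval — emulating unopacified segments —
  so `observed ⊆ truth` voxel-wise by construction.
* **The body** is an elliptic outline with a smooth cranio-caudal taper
  inside an air border. The taper matters: a z-uniform cylinder leaves
  cross-correlation blind along z (measured: NCC flat to 2 × 10⁻⁵ over
  ±4 mm) and no registration method could recover cranio-caudal shifts.
* **Texture**: a fixed smooth low-frequency field (amplitude
  `texture_amp_hu`, default 15 HU) modulates soft tissue. Real
  parenchyma is not uniform; a piecewise-constant phantom gives the
  correlation metric nothing to hold on to away from organ edges.
* **HU palette** (fixture constants, not claims about tissue): soft
  tissue 40, opacified tract 300, unopacified tract 35, lesions 80
  (configurable), air −1024. Noise is additive i.i.d. Gaussian
  (default sd 10 HU), seeded, independent between the paired volumes.
* **Misalignment**: the unenhanced volume is the analytic anatomy
  *re-rendered* at misaligned points (no interpolation artifacts), and
  the stored transform is exactly the moving-to-fixed map that
  registration should recover — parameter-recovery tests compose the
  estimate with its inverse and measure the deviation from identity.
* **Incidental lesions** are spheres whose centres must keep
  ≥ 30 mm (boundary + bridge radius) plus their own radius of clearance
  from the tract, so method-3 concealment is well-posed by construction;
  violating specs are rejected at generation time.

What the phantom deliberately does *not* emulate: organ texture, beam
hardening, partial-volume blur, anatomical variability beyond ellipsoid
jitter (`perturb_spec()`), or deformable motion. Tests passing on
phantoms therefore demonstrate algorithmic correctness — containment,
bridging guarantees, concealment, parameter recovery — not clinical
segmentation accuracy.

## The segmenter

The full-scale protocol is mirrored in `unet_config("full")`: 192 × 160
× 128 patches at 1 × 1 × 2 mm spacing, five folds, 250 epochs, RMSProp
at learning rate 1e-4, categorical Dice loss with equal class weights,
best-validation-epoch selection per fold, an averaging ensemble across
folds, and sliding-window inference with probability averaging (stride =
half patch). Architecture internals the protocol leaves open are fixed
conventionally: depth-4 U-Net, two 3 × 3 × 3 convolutions with instance
normalization and leaky-ReLU (slope 0.1) per level, nearest-neighbour
upsampling with convolution, skip concatenation, a near-zero-initialized
1 × 1 × 1 softmax head (training starts from uniform class
probabilities), no augmentation. Intensities are clipped to
[−1024, 600] HU and scaled to [0, 1].

Patch-based Dice training is well behaved when a patch covers most of
the anatomy, as it does at full scale. The desk-scale preset uses 16³
patches, and at that size several failure modes appear that the
configuration addresses explicitly; each is a documented `unet_config`
parameter:

* **Coordinate channels** (`coord_features`): three channels holding the
  patch's normalized physical position. Organs with identical
  attenuation (an opacified kidney and bladder are both ≈300 HU) are
  distinguishable only by position and shape; global coordinates let a
  small patch-based network localize them.
* **Foreground-containing crops** (`fg_crop_bias`, default 0.5): half
  the training crops are drawn uniformly among the crop origins whose
  window *contains* a random foreground voxel. Ureters occupy ≈0.1% of
  the volume; uniform crops starve the Dice loss of them. Containment —
  not centring — matters: crops that always centre the organ teach the
  network window-position artifacts, and its predictions collapse on the
  differently-offset inference tiles.
* **Variance-floored normalization** (`norm_eps`): small windows of air
  or uniform tissue have near-zero intensity variance, and plain
  instance normalization amplifies their noise to unit variance, turning
  background into hallucinated structure at inference. The preset raises
  the normalization epsilon to 0.1 so homogeneous windows stay flat; the
  floor applies identically in training and inference.
* **Auxiliary cross-entropy** (`ce_weight`, preset 1): the categorical
  Dice loss of a single small crop has a degenerate optimum — predict
  background with extreme confidence and every absent class scores
  ε/ε ≈ 1 — and RMSProp reliably finds it (observed: training loss
  ≈ 0.26, the exact degenerate value, with an all-background model).
  Mixing in a cross-entropy gradient removes that attractor. The
  full-scale preset keeps `ce_weight = 0`, i.e. the pure Dice protocol.
  Validation and best-epoch selection always use the Dice loss.
* **Polynomial learning-rate decay** (exponent 0.9, built into the
  trainer): single-crop gradients are noisy and the late epochs
  oscillate without it.

The `"small"` preset (16³ patches, depth 2, 6 base channels, 2 folds,
120 × 20 steps at learning rate 2e-2, non-overlapping inference windows)
trains a two-fold ensemble on one CPU core in roughly a quarter of an
hour. The desk-scale quality bars — mean foreground Dice ≥ 0.80 on
training phantoms, per-class Dice ≥ 0.6 for kidneys and bladder on
anatomy the fold never saw — are artifact sanity thresholds for this
package's test conditions, not reproductions of any clinical accuracy
figure. Held-out evaluation reuses the cross-validation structure: each
phantom is scored by the model of the fold that excluded it.

## Evaluation statistics

`organ_coverage()` automates the reader's visibility task: per organ
instance, the fraction of ground-truth voxels inside the focused mask.
Kidneys are split left/right by component centroid; ureters by nearest
centreline, optionally into proximal/mid/distal thirds by arc-length
fraction. On real scans those boundaries are anatomical landmarks
(renal pelvis, iliac-artery crossing); on phantoms the arc fractions
supplied by the generator stand in for them.

Coverage maps to the ordinal scales through explicit bins. The published
4-point anchors ("≤75", "75–95", "96–99", "100") overlap at their
boundaries; the implementation uses the exhaustive, disjoint reading
(−∞, .75], (.75, .95], (.95, 1), {1}, with an optional tolerance `tau`
for "complete". The 3-point scale's "miniscule parts not visible" is a
human judgment; the automated stand-in uses a configurable coverage
threshold (default 0.95).

`diagnostic_metrics()` derives sensitivity/specificity/PPV/NPV from 2×2
counts, reporting percentages to one decimal and an explicit undefined
state (`NA`) whenever a denominator is zero. `cohen_kappa()` is the
standard chance-corrected agreement for two raters of the same cases,
returning `NA` with a warning when chance agreement is 1.
`concealment_check()` reports the fraction of incidental-lesion voxels
outside a focused mask and whether all are hidden.

Two reporting conventions are implemented because published
reader-study tables use them: in multi-category visibility tables the
dominant "completely visualized" share is reported as 100 minus the
other rounded category shares (each row sums to 100.0 exactly), and
standalone case-level proportions are truncated — not rounded — to one
decimal (`case_rate_pct()`). Both are conventions of *reporting*, not of
measurement, and both are configurable by simply using the raw counts.

## Problem sizes and determinism

The test suite and the acceptance script run everything at the
`"small"` scales chosen above: 96 × 80 × 64 phantoms at 2 mm spacing,
the small U-Net preset, and a handful of registration cases. These sizes
were picked so that a full run completes on a single CPU core in tens of
minutes while still exercising every code path at meaningful resolution;
the `"standard"` phantom scale and `"full"` U-Net preset reproduce the
working-grid geometry (192 × 160 × 256 mm field of view) for users with
more compute.

Every stochastic step — phantom noise, anatomy jitter, fold assignment,
weight initialization, crop sampling — draws from a seed that is either
stored in the spec or passed explicitly, and temporary RNG state is
isolated (`with_seed`), so identical calls give bit-identical results.
The registration optimizer is deterministic given its options.

## Known limitations

* The phantom's simplicity means segmentation results do not transfer to
  clinical imagery; the segmenter module is a faithful small-scale
  implementation of the training *protocol*, not a trained clinical
  model.
* Bridging connects components by straight paths; a strongly curved
  missing ureter segment needs the 20 mm bridge radius to cover its arc,
  and a sufficiently extreme geometry could escape it.
* Cross-correlation registration assumes an approximately monotone
  intensity relationship between the paired scans; it is not a
  contrast-invariant metric, and deformable motion is out of scope.
* The 3-point "miniscule" threshold and the per-case unit of the kappa
  statistic involve judgment calls that automated scoring cannot settle;
  both are parameters, not conclusions.
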