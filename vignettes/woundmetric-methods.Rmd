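---
title: "Methods: wound planimetry and tissue classification from calibrated photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wound planimetry and tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundmetric)
```

## The measurement problem

Chronic-wound follow-up needs two quantities that are tedious to obtain at the
bedside: the wound's physical surface area (classically measured by tracing
the wound onto transparent film — planimetry) and the composition of the wound
bed by tissue type, since the proportions of necrotic, slough and granulation
tissue drive debridement and dressing decisions. `woundmetric` computes both
from an ordinary RGB photograph, provided the photograph contains a blue
2 cm × 2 cm square fiducial marker in the wound plane and the user supplies a
scribble — a rough stroke — inside the wound.

The pipeline has four stages, each usable on its own:

1. **ROI segmentation**: SLIC-style superpixels, merged from the scribble.
2. **Marker calibration**: HSV thresholding, quadrilateral fitting, geometric
   QC, and the pixel→cm² scale from the marker's known 4 cm² area.
3. **Planimetry**: wound area in cm² = ROI pixel count × scale, plus the
   tracing-agreement statistics used to validate such measurements
   (FNR, FPR, RV/ARV, Jaccard, Dice, ICC).
4. **Tissue classification**: 5 × 5-pixel patches of the preprocessed ROI
   classified by a compact convolutional network into
   necrotic / slough / granulated.

## ROI segmentation

`compute_superpixels()` is a localized k-means in the joint
(L\*, a\*, b\*, row, col) space: after a Gaussian pre-blur of width `sigma`,
cluster centres start on a regular grid of `n_segments` cells and pixels are
contested only by nearby centres with the distance
\(D^2 = d_{colour}^2 + (m/S)^2 d_{spatial}^2\), where `S` is the grid spacing
and `m` the `compactness`. Defaults are `n_segments = 100`, `sigma = 3` (the
best combination in the parameter study behind the method; the explored grid
was N ∈ {50, 100, 200} × σ ∈ {1, 3, 5}), `compactness = 10`, `max_iter = 10`
and connectivity enforcement on — standard SLIC practice. Everything is
deterministic: fixed initialisation grid, no random restarts, lowest-id
tie-breaks. CIELAB was chosen over RGB because Euclidean distances there
approximate perceptual colour differences, which is what both the clustering
and the merge threshold below rely on.

`merge_from_scribble()` grows the wound region over the superpixel adjacency
graph. A candidate superpixel is admitted when the CIELAB distance between its
mean colour and the mean colour of an already-admitted **neighbour** is below
`merge_threshold`. The admitted set is therefore the reachability set of the
scribble-touched seeds over colour-similar edges. We deliberately did *not*
use a single running region mean: a wound containing a dark necrotic core and
a bright slough ring has within-wound colour contrasts (~60 ΔE between those
two tissues under the default palette) far larger than the tissue-to-skin
contrast (~36 ΔE for slough vs skin), so no global-mean threshold can separate
wound from skin. The neighbour-chain rule admits each tissue zone along its
own colour-homogeneous chain, is deterministic, and — unlike running-mean
variants — is exactly monotone in the threshold, a property the tests assert.

**Consequence for users**: the scribble must touch every tissue zone (a single
stroke across the wound's diameter suffices for concentric zones). A scribble
confined to the necrotic core will recover only the core, because zone-to-zone
contrast exceeds the threshold by design.

The default `merge_threshold = 20` ΔE was calibrated once against the
synthetic palette: within-zone variation after superpixel averaging is ~1 ΔE
at the default noise level, while the smallest tissue-to-skin contrast is
~36 ΔE, leaving a wide margin on both sides. For unusual skin tones or tissue
palettes the threshold is a config key. The parameter study's reprocessing
path (retry with N ∈ {150, 200, 300}) is exposed as the
`segmentation.retry_n_segments` config list for the user to invoke, since no
automatic failure criterion is defined for the primary path.

`suggest_params()` carries the proposed polynomial map from image resolution
(megapixels) to (N, σ); the default (unfitted) model returns the fixed
optimum (100, 3), and fitted predictions are clipped to the explored ranges
N ∈ [50, 300], σ ∈ [1, 5].

## Marker detection and calibration

The image is converted to hexcone HSV and thresholded to "shades of blue"
(defaults: hue 200–260°, saturation ≥ 0.35, value ≥ 0.20). Each connected
blue component's outer contour is simplified to a quadrilateral by
Ramer–Douglas–Peucker with tolerance 2% of the perimeter, relaxed stepwise to
5%; components that never reach exactly 4 vertices, or are smaller than
`min_area_px` (default 400), are dropped. Among the surviving candidates the
one minimising |quad area − mask area| / mask area is selected — the
"closest to a rectangle" rule. The original protocol's clause about "lengths
greater than twice their breadth" is contradictory for a square marker; we
read it as a minimum-size gate plus an aspect window, implemented as
`min_area_px` together with the proportionality QC.

Two geometric scores validate placement:

* **proportionality** = shortest side / longest side (1 for a perfect square);
* **asymmetry** = max of the top/bottom and left/right relative side-length
  disparities — exactly 0 for any parallelogram (hence for any in-plane
  rotation) and growing with perspective foreshortening.

Defaults `min_proportionality = 0.8` and `max_asymmetry = 0.2` encode the
protocol's "close to 1" / "towards 0" guidance as concrete gates. When the
marker passes, the scale is `4 / quad_area_px` cm²/px and the wound area is
`ROI pixels × scale`. A rejected marker does not produce an area at all: the
capture protocol treats an inclined or occluded marker as a retake, so no
homography rectification is attempted (a limitation, not an oversight: within
the accepted QC envelope the raw-quadrilateral scale error is below ~2%).

Two half-pixel conventions make the calibration exact rather than
approximately right. The synthetic renderer fills polygons half-open in both
axes, so a lattice-aligned square of side *s* covers exactly *s*² pixels; and
because a traced contour runs through pixel *centres* (underestimating the
covered extent by half a pixel per side), each fitted corner is pushed
outward 0.5 px along its two adjacent edges. A rendered side-100 marker then
calibrates to exactly 4 × 10⁻⁴ cm²/px, and a 100 × 40 rectangle scores
proportionality exactly 0.4.

## Agreement metrics

With `R` the reference tracing area, `T` the test tracing area and `O` their
overlap, `compare_tracings()` reports

* FNR = 100 (R − O) / R, FPR = 100 (T − O) / R, RV = 100 (T − R) / R,
* ARV = |RV|, Jaccard = O / (R + T − O), Dice = 2O / (R + T).

All printed expressions of the form `100 × T − O / R` are read with the
numerator parenthesised, consistent with "normalisation by the reference
tracing's size". RV is kept signed with ARV exposed separately, since both
readings are useful. When both tracings are empty (full epithelialisation on
both) the pair is non-comparable and excluded from summaries; when only the
reference is empty the reference-normalised metrics are undefined, and the
pair is flagged degenerate with FPR reported against `T` instead. Note ARV's
designed blind spot: two disjoint tracings of equal area score ARV = 0.

`icc_absolute_agreement()` is ICC(2,1): two-way random effects, absolute
agreement, single measurement. This variant was chosen over consistency-type
ICCs because systematic offsets between measurement methods must count
against agreement when validating a new device against planimetry. It is
computed from the standard mean-squares decomposition and cross-checked in
the tests against `stats::aov` mean squares.

## Tissue classification

Preprocessing mirrors the protocol: black mask outside the ROI, crop to the
ROI bounding box, bilinear resize to 200 × 200, intensities in [0, 1]; the
label mask follows the identical geometry with nearest-neighbour resampling
so labels stay integral. The raster is cut into the non-overlapping 40 × 40
grid of 5 × 5 patches ("sections measuring 5 × 5 pixels" is read as
pixels-per-patch; the patch side is an argument for the alternative reading);
each patch is labelled by majority tissue, and patches more than half
background are dropped. Augmentation adds a horizontal flip and a zoom
resample (factor U[0.9, 1.1]) per training patch; the 80/20 split is
stratified by class and assigned at the scene level so no source image leaks
across splits (scene granularity permitting — with one example per scene the
per-class split is exact to one example).

The classifier is a compact network trained from scratch: two 3 × 3
convolutions (8 and 16 filters, valid padding, ReLU) followed by exactly the
described head — flatten, dense ReLU (32 units), dropout 0.3, dense softmax.
At 5 × 5-patch scale colour is the dominant, and nearly sufficient, signal —
which matches the clinical rationale that tissue proportions are judged by
colour — so a large pretrained backbone would add nothing here; an
instance-segmentation network is out of scope by design, and the model
accepts any drop-in feature extractor of the same interface. Training is
plain mini-batch SGD (rate 0.05, batch 64, ≤ 60 epochs by default) on the
mean tissue cross-entropy
\(L_t = -\sum_k z_k \log p_k\), with probabilities clamped at 1e−12 before
the log, early-stopped on a held-out 10% of the training split (patience 10),
and fully deterministic under the configuration seed. The combined objective
\(J = \sum_i (L_{s,i} + L_{t,i})\) adds a size-category cross-entropy; the
size branch itself is the deterministic thresholding rule
`size_category()` (defaults: small < 5 cm² ≤ medium < 20 cm² ≤ large —
thresholds are configuration, as no canonical clinical bins exist), so its
loss term is exercised as a function rather than trained.

Evaluation reports the per-class precision/recall/F1, their unweighted macro
averages, the confusion matrix and overall accuracy; a class absent from the
test set yields NaN recall with a warning rather than a silent 0.

## The synthetic scene generator

No clinical images ship with the package, so `render_scene()` produces the
test substrate: a skin-toned background, a wound blob whose boundary is a
radially perturbed ellipse (low-order cosine harmonics, amplitude
`boundary_roughness`), concentric tissue zones (necrotic core, slough ring,
granulation rim) whose areas match `tissue_mix` exactly in the continuum
(zones are thresholds on the squared normalised radius), and a blue square
marker rendered under in-plane rotation and an optional one-parameter
perspective foreshortening, with global illumination gain and additive
Gaussian sensor noise (default sd 5 of 255). Defaults: 300 × 400 frame,
wound radii (80, 60) px, roughness 0.15, mix (0.2, 0.3, 0.5), marker side
60 px, hue 225°. Two seeds separate concerns: `seed` drives only the sensor
noise, `shape_seed` the boundary harmonics, so re-rendering with a new `seed`
never changes the ground-truth masks.

What the generator deliberately does **not** emulate: specular highlights,
shadows and non-uniform illumination fields, lens distortion, motion blur,
skin texture, depigmented or macerated peri-wound skin, tissue colour
gradients within a zone, and non-planar wound surfaces. Passing tests on this
substrate therefore demonstrate the *internal correctness* of the pipeline —
exact metric arithmetic, exact calibration geometry, monotone and
deterministic segmentation, a learnable colour-to-tissue mapping — not
clinical accuracy on real photographs, which depends on colour constancy and
capture discipline the synthetic scenes idealise.

## Numerical choices and degenerate inputs

* Coordinates are row-major and 0-based everywhere; masks are logical
  matrices; images are 8-bit RGB arrays.
* k-means assignment ties go to the lowest centre id; superpixel fragments
  orphaned by connectivity enforcement join their largest adjacent
  superpixel.
* `merge_threshold` comparisons are strict (`<`), so threshold 0 returns
  exactly the scribble-touched superpixels and ∞ the whole frame.
* Empty ROI, empty training classes, dimension mismatches, markers outside
  the frame or overlapping the wound, scribbles outside the image, and
  diverging training losses all raise classed errors (`input_error`,
  `geometry_error`, `parameter_error`, `training_error`, ...), never silent
  NA propagation.
* An all-constant rater table makes the ICC undefined: NaN with a warning.

## Problem sizes

Module tests run on reduced 150 × 220 scenes with ~60 superpixels; the
end-to-end checks use the full default 300 × 400 scenes at (N = 100, σ = 3)
over 20 seeds for segmentation recovery, a 24-train / 6-test scene split with
up to 200 patches per scene (5 training seeds) for the classifier, and
500-row simulated rater tables for ICC recovery. These sizes were chosen so
the whole suite documents the pipeline's behaviour in a few minutes on a
single CPU while keeping every check statistically comfortable.

## Known limitations

* Calibration assumes the marker lies in the wound plane; out-of-plane wounds
  (deep cavities, curved limbs) violate the single-scale assumption.
* No homography rectification: markers beyond the QC envelope are rejected,
  not corrected.
* The classifier is trained on synthetic palettes; applying it to real
  photographs requires retraining on labelled clinical patches
  (`train_tissue_model()` accepts any `tissue_dataset`).
* Hue-gate marker detection can fail under strong colour casts; the gate is
  configurable but not adaptive.
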