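---
title: "Methods: card-anchored meal volumetry and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: card-anchored meal volumetry and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mealmetry` measures food volume from depth-annotated meal images and maps
it to energy and macronutrients. This vignette explains the measurement
model, the choices that were genuinely open when the package was designed,
and what the synthetic test bed does and does not establish about real
images.

## The measurement model

A single photo carries no absolute scale. The system therefore assumes a
flat reference card of known physical size (default 85.6 × 54.0 mm, the
credit-card format, configurable) lying flush on the table beside the food.
Everything metric flows from that card:

1. **Card pose.** The detector finds the card's four corners; the
   homography between the metric card rectangle and those corners,
   decomposed with the camera intrinsics, gives the card plane's pose. Of
   the two algebraic pose solutions we keep the one with the card in front
   of the camera and its normal facing it.
2. **Depth alignment.** A pluggable single-image depth provider may return
   depth in arbitrary units. The pose predicts the true optical-axis depth
   of the card centre; dividing that prediction by the *median* observed
   depth over the card region gives one global scale. The median rather
   than the mean makes the anchor robust to speckle outliers. Depth is
   defined throughout as distance along the optical axis, so the alignment
   ratio compares like with like; an already-metric provider gets a scale
   of ~1, which is still applied.
3. **Per-item volume.** Masked depth pixels back-project with the pinhole
   equations into the camera frame, then into the card frame (card plane at
   z = 0, +z toward the camera). Single-view depth observes only each
   item's *top surface*, so the faithful volume model is a height field
   above the table plane: the plan view is partitioned into 2-mm cells,
   each cell's height is the median z of its points, and volume is
   `Σ cell_area × height`. Empty cells contribute zero — no inpainting —
   which keeps the estimator simple and testable.
4. **Plausibility rules.** Before integration, points more than 5 mm below
   the card plane or more than 50 mm above it are discarded (food sits on
   the table and seldom rises above 5 cm); remaining negative heights clip
   to zero; a k-nearest-neighbour statistical filter (k = 20, cutoff mean +
   2 sd of the mean-neighbour-distance statistic) removes speckle; and no
   single item may exceed 2.5 cups, with 1 cup = 240 mL (the nutrition-label
   cup), i.e. 600 mL. If the card is missing or any stage degenerates, the
   item falls back to its standard serving volume from the nutrient table —
   a deliberate "never crash on a missing card" contract.

### Two-view (geometry) depth

The alternative back-end computes depth from two views, nominally at 90°
and 75° elevation. From ≥ 8 point correspondences (card corners, card edge
midpoints and centre, and per-solid top-surface keypoints) the fundamental
matrix is estimated with the normalised 8-point algorithm. Because the
intrinsics are known, we upgrade it to an essential matrix, decompose the
relative pose (cheirality-tested), and build a *calibrated* rectification
whose new x-axis lies along the baseline. This choice matters: with a
calibrated rectification the textbook relation `Z = f·B/d` is exact in the
rectified frame, so the disparity-to-depth conversion needs no empirical
fudge. Disparity itself is plain block matching — per pixel, the integer
offset minimising the sum of absolute differences over an 11-px block, with
a 5% uniqueness margin marking ambiguous (textureless) pixels invalid, and
border pixels whose search range was truncated likewise invalid. Integer
disparities keep the quantisation bound `f·B·(1/d − 1/(d+1))` exact, which
the tests rely on. The physical baseline is unknown on a phone, so it is
derived from the card poses estimated independently in the two views; the
rectified depth is finally resampled into the first view's pixel grid so
the volume pipeline is back-end agnostic.

Off-plane keypoints are included in the correspondence set on purpose:
correspondences confined to the table plane are a degenerate input for
fundamental-matrix estimation (a plane induces only a homography).

## Nutrients

`weight = volume × density`, then each nutrient is `weight × per-100 g /
100`. Tables are plain CSV with a primary → secondary lookup order; network
nutrient databases are deliberately out of scope because they are not a
reproducible test surface, but the fallback *order* is preserved as
behaviour, and secondary hits are flagged. Packaged products bypass
volumetry: their per-package nutrients are scaled by the user-declared
fraction consumed, gated by an EAN-13 checksum. Zero-energy drinks (water)
carry explicit records rather than being skipped. The bundled fixture table
covers the 20-category miniature taxonomy with label-convention values; the
olive-oil record is set to 8.0 kcal/g and 0.90 fat fraction so that 50 g of
oil maps to 400 kcal and 45 g of fat. All fixture records satisfy Atwater
consistency (|kcal − (4·CHO + 4·protein + 9·fat)| < 15% of kcal) where
kcal > 0.

## Study-level evaluation

Daily totals per participant are compared to reference intakes with the
absolute percentage error `100·|est − ref|/ref`; the study summary is the
mean and *sample* (n − 1) standard deviation across participants, with a
single participant reported as sd 0 plus a warning so tiny fixtures stay
runnable. Method comparison uses Welch's unpaired t-test (the variances of
two pipelines' APEs have no reason to be equal); two identical
zero-variance lists are reported as t = 0, p = 1 by convention. Bland–Altman
limits of agreement use the 1.96 multiplier for 95% limits.

## The synthetic scene generator

The generator is first-class code, not a fixture dump. A scene is a flat
table at z = 0, a zero-thickness card, and parametric solids — cuboid,
cylinder, spherical cap, conical frustum — each with a closed-form volume.
The renderer casts exact rays: per pixel, the analytic ray/solid or
ray/plane intersection along the optical axis, so renders are ground truth
to machine precision, with per-item masks, exact card-corner projections,
and an intensity channel whose procedural texture is anchored to *world*
coordinates so it is consistent across viewpoints (which is what block
matching needs). Degradation is modelled as per-pixel Gaussian depth noise
plus a deterministic count `round(frac · n_valid)` of gross uniform
outliers, fully seeded.

The synthetic study emulates a one-day feasibility protocol: each
participant draws meals from a scene catalogue; the daily truth is the
analytic nutrient content; the "dietitian recall" reference multiplies
truth by log-normal noise with unit mean and a configurable coefficient of
variation, drawn independently per participant and nutrient. The default
noise CV of 0.10 is a deliberately mild recall-error model: it yields a
per-nutrient MAPE of about 8% under a perfect pipeline (for a unit-mean
log-normal with CV 0.10, E|X−1| ≈ 0.08), which the acceptance checks
verify as a 7–13% band at n = 200.

What the synthetic bed does **not** show: robustness to real segmentation
errors, occlusion between items, specularity, motion blur, lens distortion,
or learned-depth biases. The perception contracts (mask lists, ranked
predictions, the top-5 user-selection rule) accept any external model's
outputs, but the bundled segmenter reads the renderer's index channel and
the bundled classifier is an oracle with a configurable truth rank — they
exist to make the *measurement* chain testable end to end, not to claim
recognition performance.

## Numerical choices and degenerate inputs

* Pixels are 0-based cell centres; depth is optical-axis distance, not ray
  length — both back-projection and rendering share this convention, so
  round trips are exact.
* Card detection thresholds the renderer's near-white card band, simplifies
  the component hull to a quadrilateral (iteratively removing the
  minimum-area vertex), refines each edge by a total-least-squares line fit
  to boundary pixels shifted half a pixel outward (the sampling bias of
  pixel centres), and intersects adjacent edges. Ties between candidate
  quadrilaterals break by rectangularity × area. Corner ordering starts on
  a long edge; the residual two-fold ambiguity of a plain rectangle is
  resolved by a deterministic tie-break and is harmless because the pose is
  symmetric under it.
* Collinear corners raise a pose error; a card fully outside the frustum is
  an unusable fixture and errors early; a missing card at run time is *not*
  an error but the documented serving fallback.
* The statistical filter's grid-hash neighbour search sizes its cells from
  robust (1st/99th percentile) extents so that gross depth outliers cannot
  degrade it, and falls back to exact brute force for isolated points.
* Depth rasters serialise as single-channel 16-bit TIFF at 1/16 mm
  quantisation with 0 = invalid and a JSON sidecar for the camera;
  masks as 8-bit indexed TIFF; reports as versioned JSON with numbers at 6
  significant digits so equal runs are byte-identical. Configuration files
  are YAML.
* In the scale-equivariance check, the rule constants (height band, cup
  size, grid cell) are scaled together with the scene: the property under
  test is that the card anchors the metric chain, so the *entire* world,
  including the measurement rules, scales — otherwise the fixed 5/50 mm
  band would clip a scaled scene and the property would conflate two
  effects.

## Problem sizes

The test suite and acceptance script run renders at 640 × 480 (fx = 800,
camera at 400 mm) for the reference-solid recoveries and the stereo
back-end, 320 × 240 for the 20-scene equivariance sweep, a 200-participant
synthetic study for the statistics, and 20 noise seeds for the degradation
check — sizes chosen so the whole suite completes in a few minutes on one
CPU while keeping every estimate's sampling error well below the tolerances
being asserted.

## Known limitations

* Height-field integration cannot see overhangs or cavities; a hollow cup
  reads as full. This is inherent to single-view depth, not an
  implementation defect.
* Vertical side walls are observed only at glancing angles; rim pixels
  inflate cylinder volumes by a few percent at 90° elevation.
* A widening-downward frustum self-occludes under oblique views and is
  underestimated by up to ~10%; the reference recovery checks use shapes
  whose visible surface determines the volume.
* The 2-fold corner ambiguity means the card frame's in-plane axes are
  arbitrary; only the plane and its normal are meaningful.
* The stereo matcher is integer-disparity SAD by design (the simplest
  faithful reading of row-wise comparison); sub-pixel refinement would
  roughly halve the quantisation error but would complicate the exact
  error-bound tests.
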