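---
title: "Counting plants in 3D canopy scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting plants in 3D canopy scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopycount)
```

## The problem

High-throughput phenotyping platforms scan rows of plant trays with a
line-laser from above and merge the height profiles into a 3D point cloud
(roughly 0.8 × 0.8 × 0.2 mm resolution in x, y, z). Each tray holds a single
genotype with a handful of plants (0–8), and many downstream analyses —
starting with simply counting the plants — need *individual* plants
separated from soil, tray frames and scanner clutter. Counting by hand is
slow and error-prone; `canopycount` automates it in five steps:

1. **Tray splitting** — the scan row is divided into equal intervals along
   the lineup (y) axis, one per tray, and the tray rim is stripped.
2. **Soil segmentation** — plant points are separated from soil, by region
   growing over surface normals (default) or by RANSAC plane consensus.
3. **Rasterization** — after statistical outlier removal, the plant cloud
   is projected to a 2D image whose colors encode height (blue low, green
   mid, red high), the representation a 2D object detector consumes.
4. **Detection** — a pluggable detector proposes boxes; its raw output is
   post-filtered by confidence, greedy overlap suppression, and a
   per-class cap.
5. **Counting and evaluation** — boxes are counted per tray; against
   ground truth the package reports IoU-based precision/recall, COCO-style
   mAP, and the MAPE of the per-tray counts (accuracy = 100 − MAPE).

## Why not a fixed height threshold?

Soil is not flat: trays hold less soil in the middle than at the sides
(a bowl, here modelled with ~15 mm amplitude), and mean soil level differs
between trays. A single z cut therefore either keeps side soil or discards
the lower parts of plants — late-germinated plants sitting inside the bowl
can lie entirely *below* the soil level at the tray sides, so no cut
recovers them. The acceptance suite reproduces this quantitatively: on a
bowl-soil scene with short plants, the best possible fixed cut retains at
least five times more soil (or loses at least five times more plant
points) than region growing.

## Soil segmentation

**Surface normals and curvature.** For every point the covariance of its
k nearest neighbours (point included) is eigen-decomposed; the normal is
the eigenvector of the smallest eigenvalue λ₀ and the curvature is the
surface variation λ₀/(λ₀+λ₁+λ₂) (0 on a plane, up to 1/3 for isotropic
scatter). Normals are reported with a non-negative z component; surfaces
that are exactly vertical (|n_z| below 1e−9, the numerical zero for unit
eigenvectors) are oriented by +y, then +x. k-NN neighbourhoods (default
k = 30) are used rather than a fixed radius because the scanner's density
is strongly anisotropic (x–y spacing four times the z quantization).

**Region growing.** Points are visited by ascending curvature; each
still-unlabelled point seeds a region grown breadth-first over k-NN
neighbourhoods. A neighbour joins when the angle between its normal and
the normal of the point currently being expanded is below the smoothness
threshold (default 3°), and itself keeps expanding the front when its
curvature is below the curvature threshold (default 1, i.e. effectively
always, appropriate when surfaces meet across gaps rather than sharp
creases; tighten it to ~0.01 to stop growth at crease edges, as the
plane-plus-wall tests do). Regions below `min_cluster_size` (default 50)
are left unclustered (label −1). The largest cluster is declared soil —
in a frame-cleaned tray the soil surface is always the dominant smooth
surface. Comparing against the expanding point's normal (rather than a
running region average) keeps the procedure deterministic and
order-independent given the curvature ordering; ties between equally
large clusters go to the lower label.

After removing the soil cluster, the remaining *clustered* points are
plants. Unclustered points are kept only when they lie above the soil
cluster's 95th z percentile: small, sparsely sampled plants must survive,
while low-lying unclustered noise should not.

**RANSAC alternative.** 3-point hypotheses are sampled for a fixed number
of iterations (default 1000); the plane with the most points within the
distance threshold (default 2.5 mm) wins, is refit to its inliers by total
least squares, and the inlier set is recomputed once. With a fixed seed
the result is bit-reproducible, and more iterations can only improve the
consensus. On bowl-shaped soil a single plane cannot hug the surface, so
some soil survives as "plant" — the behaviour that makes region growing
the preferred default; the two methods nevertheless retain almost the
same *plant* set (within 3 percentage points on synthetic trays).

## Rasterization

Statistical outlier removal (k = 16, cut-off mean + 2 sd of the mean k-NN
distances) drops sparse clutter before projection. Pixels take the
maximum z of their points — the canopy-surface view matching a scanner
looking from above; mean-z would blur leaf edges. Height is normalised
per tray (soil levels and plant heights differ between trays) and mapped
blue → green → red piecewise-linearly, with pure blue at the tray's
minimum height and pure red at its maximum; a degenerate tray (z_max =
z_min) maps everything to blue. Black (0, 0, 0) is reserved for
background so empty areas carry no texture whatsoever — object detectors
are sensitive to spurious background patterns. The default pixel size is
0.8 mm, the scanner's x–y resolution, i.e. about one point per pixel;
when the input is sampled more coarsely (as the synthetic scenes are, at
3 mm) the pixel size should be set to match, otherwise each point lights
an isolated pixel and connected structures fall apart.

## Detection

The detection stage is detector-agnostic. The package ships a classical
baseline — 8-connected components of the plant mask, one box per
component of at least `min_area_px` pixels, confidence
min(1, area/`area_ref_px`) — and an adapter that loads CSV detections
produced by any externally trained model (e.g. a fine-tuned two-stage
CNN). Training a CNN is out of scope here; what the pipeline owns is the
post-processing every detector shares, with defaults carried by
`detector_config()`: score threshold 0.5, overlap (IoU) threshold 0.2
for greedy non-maximum suppression, and at most 10 detections per class
per image (a tray physically holds few plants). Aspect ratios
(0.5, 1, 2) are stored for CNN region proposals and unused by the
baseline.

## Evaluation

IoU is exact rectangle algebra on half-open pixel boxes. Matching is
greedy in descending score order against the unmatched ground-truth box
of highest IoU, with a *strict* inequality at the threshold (IoU exactly
equal to the threshold is not a match) and IoU ties resolved to the lower
ground-truth index. AP uses the 101-point interpolated sweep and mAP
averages the ten thresholds 0.50–0.95; a detection set built to overlap
its ground truth at IoU exactly 0.6 scores mAP 0.2 (AP 1 at thresholds
0.50 and 0.55 only), which the tests assert. Counting accuracy is MAPE
over trays with a positive manual count; zero-truth trays cannot enter a
relative error and are reported separately as false detections on empty
trays. Missed plants are counted as false negatives (the standard
detection semantics; "true negatives" are undefined for detectors and not
reported).

## The synthetic scene generator

`generate_scene()` emulates the platform geometry so every stage is
testable without proprietary scans: trays lined along y; soil on a
jittered grid with a sinusoidal bowl (default depth 15 mm, the middle
lower than the sides) plus 1 mm Gaussian roughness; a raised rim of the
frame width; plants as a vertical stem plus 3–6 elliptical leaf disks
anchored at the *local* soil surface (so short plants sit inside the
bowl); and a configurable fraction of uniform clutter (default 1%).
Plant centres are rejection-sampled at least two maximum leaf radii
apart — the non-overlapping regime in which one plant maps to one
connected raster component. All draws come from one seeded RNG stream in
a fixed order, so a spec plus seed is bit-reproducible.

Defaults mirror the study conditions the pipeline targets: 12 trays per
scan row of 640 × 400 mm (20 mm frame), 0–8 plants per tray, heights
60–160 mm. The sampling grid is 3 mm rather than the scanner's 0.8 mm —
the package's chosen desk-scale density, keeping a 30-tray scene under a
million points while leaving >500 points per plant; the matching raster
configuration is `pixel_size_mm = 3` with `area_ref_px = 100`
(≈ 900 mm²). What the generator does *not* model: laser radiometry
(intensity is read from files but never used), occlusion from the 45°
camera geometry, touching or overlapping plants, and real leaf
morphology. Passing tests therefore demonstrate the pipeline's geometric
and statistical correctness, not detection performance on real crops —
on real scans the detector stage is expected to be an externally trained
CNN entering through the adapter.

## Numerical choices and degenerate inputs

* Tray intervals are computed from the observed y extent, half-open with
  the last closed; boundary points go to the higher-index tray. Frame
  removal measures margins from the observed bounding rectangle and tags
  its output so re-application is a no-op (re-deriving the rectangle from
  a stripped cloud would peel a fresh band each time).
* Eigen-decompositions of the 3×3 neighbourhood covariances use a
  symmetric solver; clouds smaller than k+1 points are rejected for
  normal estimation, and trays too sparse to segment return an empty
  plant set rather than an error.
* RANSAC skips collinear samples; fewer than 3 points (or all samples
  collinear) is a degenerate-geometry error. Hypothesis ties keep the
  earlier iteration.
* SOR on clouds with ≤ k points returns the input unchanged with a
  warning; score ties in detection filtering and matching are broken by
  input order, making every stage deterministic.
* MAPE over trays that are all zero-truth is an error, not 0/0.

## Problem sizes used by the tests

The test and acceptance suites run the geometry checks at fixed sizes
chosen as the package's own benchmark scales: the tilted-plane RANSAC
recovery on ~12,000 points (20% clutter, σ = 0.2 mm noise, 1 mm
threshold, 500 iterations); the plane-plus-wall region-growing check on
~60,000 points; SOR against an exhaustive-distance oracle on fifty
2,000-point clouds; metric oracles on 200 random scenes of up to 8
boxes; and end-to-end counting on a 30-tray scene (~1M points) with 0–8
plants per tray, where the pipeline is required to stay within 10% MAPE
and to produce no detections on empty trays of clutter-free scenes.
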