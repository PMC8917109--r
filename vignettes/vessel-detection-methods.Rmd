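---
title: "Vessel detection in immunofluorescence sections: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel detection methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvdetect)
```

## The problem and the model

Immunofluorescence staining of tissue sections labels vessel walls
(endothelium via CD31, smooth muscle via αSMA) as bright red/green
structures on a near-black background. Vessels appear as filled
profiles, as rings with a dark lumen, or as elongated profiles when cut
longitudinally. `bvdetect` treats detection as a segmentation problem
with a fixed, deterministic operator chain rather than a learned model:
every stage is a classical image operation with a small number of
interpretable parameters, and the output is a pure function of the
image and the parameter set. This buys reproducibility and
auditability — the properties that matter most when counts feed
group comparisons — at the cost of the flexibility a trained model
would have on unusual stains.

The assumptions the pipeline relies on are: stained vessels are
brighter than the background in the selected channel; background
suppression by the IF protocol is reasonable (chromogenic/H&E material
violates this and is out of scope); vessels of interest occupy an area
band that excludes speckle noise below and section-wide artifacts
above; and lumened vessels present an approximately circular wall.

## Stages and the parameters that matter

**Normalization.** One global min–max map to [0, 1] across all
channels jointly. A per-channel map would silently rescale relative
stain intensities; a joint map preserves them. A constant (blank)
acquisition yields an all-zero image plus a warning flag rather than an
error, so batch runs survive.

**Channel.** `channel` ∈ {red, green}, explicit, never inferred: which
stain marks vessels is an experimental-design fact the software cannot
know.

**Smoothing.** 3×3 mean filter, replicate padding. Replicate padding
makes constant images fixed points and avoids the darkened borders a
zero-padded filter produces; the kernel is fixed because the
thresholding stage, not the filter, carries the adaptivity.

**Threshold.** Otsu's criterion on a 256-bin histogram of [0, 1]. The
implementation returns k/256 where k is the split index maximizing
between-class variance, with ties broken toward the smallest index —
stated explicitly because Otsu conventions (bin centers vs. edges,
tie handling) differ across libraries and would otherwise make runs
non-comparable. A manual `threshold` in [0, 1] overrides the
suggestion, mirroring interactive use where an operator tunes the
segmentation by visual feedback.

**Connectivity.** Foreground components are 8-connected (edge or
corner adjacency); background, for hole filling and the lumen rule, is
4-connected. The complementary pairing is the standard duality that
prevents a fill from leaking through a diagonal wall gap.

**Area band.** `min_area_px = 50` and `max_area_px` = 10 % of the
image pixel count by default. At the magnifications typical for these
datasets (≈ 0.5 µm/px) 50 px ≈ 12.5 µm², below any capillary
cross-section, and the upper bound removes only section-scale staining
artifacts. Both are deliberately coarse and user-overridable; they are
screens, not the detector.

**Lumen recovery.** Thin-walled small vessels are mostly lumen: their
ring component can fall below `min_area_px` even though the vessel is
real. Removed-small components are reconsidered: a circular Hough
transform over the binary mask proposes circles (radius range
[5, 50] px, acceptance score ≥ 0.3 of the perimeter vote), and a
component returns when it overlaps a circle and encloses a hollow
region inside that circle whose area is *strictly* greater than
`lumen_fraction = 0.125` of the component area. The inequality is
strict by definition of the rule; at exactly 12.5 % the component
stays removed. The Hough accumulator votes along full circle
perimeters rather than along gradient rays: on a binary mask, gradient
directions are quantized to eight angles, and full-perimeter voting
with a perimeter-normalized score proved the more robust accumulator
for rasterized rings. The recovery search runs only when some removed
component actually encloses a hole, which keeps the common case cheap.

**Closing and filling.** Closing uses a 3×3 square structuring
element; dilation treats out-of-bounds pixels as background and
erosion as foreground, the convention that keeps closing extensive at
the image frame. Filling then converts enclosed background into
foreground so the reported vessel area includes the lumen. Closing is
extensive, so no retained component can drop below the area band here;
it can merge vessels closer than ~2 px, which is a declared limitation
(the method does not split touching vessels).

**Morphometry.** Descriptors come from raw and central second moments
with each pixel treated as a unit square: the covariance gets +1/12
per-pixel variance, axis lengths are 4·√eigenvalue, eccentricity
√(1 − (minor/major)²), orientation in (−90°, 90°] between the column
axis and the major axis. This matches the convention of the
`regionprops` family so values are comparable with the wider
literature. Perimeter is the length of the traced outer boundary
contour through pixel centers (Moore neighbor tracing; edge steps 1,
diagonal steps √2; a single pixel has perimeter 0) — perimeter
definitions differ across libraries by design, so ours is documented
rather than assumed. Coordinates are R's native 1-based (row, col)
with origin top-left; all derived quantities are index-origin
independent.

## Evaluation statistics

Matching is greedy one-to-one: candidate pairs are detections whose
centroid lies inside a truth region or within `max_dist_px = 20` px
(≈ 10 µm at 0.5 µm/px) of a truth centroid, accepted in ascending
distance, each object used once. This mirrors how a human checks
whether a marker points at the same vessel, and guarantees
TP + FP = detections and TP + FN = truth. Precision, recall and
F-measure follow their defining ratios, with 0/0 reported as 0 and
flagged. Batch metrics are reported both micro-averaged (counts pooled
before the ratios — the primary number) and macro-averaged (per-image
metrics averaged), since the two differ when image difficulty varies
and published figures do not always say which was used.

Bland–Altman agreement uses the sample (n−1) SD and 1.96 (not 2) for
the limits, with the pairwise mean as abscissa. Zero-variance inputs
flag the correlation as undefined rather than erroring. CTGF is the
exact subtraction formula and may legitimately be negative.

## The phantom generator

The generator emulates the validation strategy of compositing known
vessel structures on a black background: parametric solid
blobs (ellipses, axis ratio 0.7–1), annuli (inner radius 0.45–0.7 of
the outer, which makes the rasterized lumen fraction ≥ 0.25, safely
above the 12.5 % rule), and bent capsules for longitudinal profiles,
at per-object intensities 0.6–1.0 in one channel, with additive
clipped Gaussian noise (default σ = 0.02) and optional labeled
artifacts (bright fold streaks, low-intensity haze gradients,
off-channel blotches). Parametric shapes were chosen over crops of
real images because they give exact analytic ground truth with no
external data dependency.

`min_separation_px` is enforced as the minimum edge-to-edge background
gap between rendered objects (which bounds the centroid separation
from below a fortiori); placement is rejection sampling, largest
bounding radius first, erroring after 500 failed tries rather than
silently dropping objects. Defaults — 512×512 frames, radii 6–30 px,
0.4/0.3/0.3 shape mix, 15 px gaps, σ = 0.02 — are the batch conditions
used throughout validation; `phantom_batch()` draws 15–40 vessels per
image under a per-image seed ladder so the whole batch derives from
one seed.

What the phantoms do **not** emulate: tissue autofluorescence texture,
intensity falloff inside thick sections, touching or overlapping
vessels, partial-volume edges, and chromogenic stains. Perfect scores
on phantoms therefore demonstrate correctness of the pipeline's logic
and its behavior at its decision boundaries, not field performance on
real tissue, where published operating points are substantially below
100 %.

## Numerical choices and degenerate inputs

- Otsu ties → smallest bin index; single-valued histogram → T = 0 with
  a warning (consistent with the all-zero degenerate normalization).
- Binarization is strictly `> T`, so T = 1 yields an empty mask.
- Component order is the raster-scan order of each component's first
  pixel, making labelings reproducible across runs and platforms.
- Density maps: centroids binned at `bin_size_px = 32`, smoothed with
  a Gaussian of σ = 1.5 bins whose kernel is renormalized per source
  cell over the in-bounds grid, so total mass equals the centroid
  count exactly (machine precision) even at borders; σ = 0 disables
  smoothing. Sections are assumed pre-registered; no registration is
  attempted.
- Label masks are written as 16-bit TIFF (lossless for ≤ 65535
  labels); overlays as 8-bit PNG.
- The RNG state of the caller is saved and restored around phantom
  generation, so seeded generation never perturbs a surrounding
  analysis.

## Problem sizes in the test suite

The suite validates the labeling against an independent
label-propagation oracle exhaustively on all 65 536 4×4 masks and on
random 32×32 masks; moment descriptors against a numerical
eigendecomposition oracle on random small regions; Otsu against a
value-space intra-class variance scan on bin-center-valued images; and
the full pipeline on 10-image batches of 512×512 phantoms (15–40
vessels each), which run in a few seconds on one CPU. These sizes were
chosen to keep the suite fast while covering every decision boundary
(strict 12.5 % rule, inclusive area bounds, corner adjacency,
border-touching background).

## Known limitations

- Touching vessels closer than the closing scale are merged, not
  split.
- Longitudinal sections are detected but their morphometry is tuned
  for round profiles; accuracy is sub-optimal for strongly elongated
  vessels.
- Chromogenic (DAB/H&E/Masson) images are unsupported by design.
- ROI isolation is the operator's job; the package analyzes the frame
  it is given.
- The Hough recovery assumes approximately circular lumina; highly
  elliptical lumina of removed-small components may not be recovered.
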