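---
title: "Semantic autofocus for liquid-based cytology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic autofocus for liquid-based cytology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cytofocus)
```

## The scanning problem

Liquid-based cytology slides carry their cells inside a circular
deposition area as a thin three-dimensional gel: focus-point heights vary
by tens of micrometres within one slide, and every slide sits at a
different absolute height. A slide scanner samples this surface at a set
of focus points, interpolates a focus map, and scans along it. Two things
go wrong in practice. First, contrast-based autofocus cannot tell cells
from coverslip dust, so focus points land on a second, spurious focal
plane well above the cell layer. Second, even with clean points, too few
or badly placed points under-sample the height profile and parts of the
scan come out blurry. `cytofocus` models both failure modes and the
control loop that fixes them, entirely against a simulator, so every
claim is testable with known ground truth.

## The virtual slide

`make_virtual_slide()` draws `n_cells` cell records uniformly inside the
cell circle. Each record carries position, an ellipse geometry, a stain
class (hematoxylin-blue, DAB-brown/p16, or Fast-Red/Ki-67, at 60/20/20%),
per-cell HSV jitter within the class palette, and a cluster flag (15% of
deposits render as three overlapping ellipses). The focal surface is a
bilinear interpolation of a small control grid of random heights rescaled
to the requested peak-to-peak range, plus a base offset of 100 µm
standing in for the normalized objective distance. Dust particles are
gray (zero-saturation) ellipses on a plane
`dust_layer_offset_um` *nearer the objective* than the lowest cell; the
two layers are disjoint by construction.

Defocus is Gaussian blur with sigma linear in the absolute z-offset,
`sigma = min(0.5 px/µm × |Δz|, 10 px)`. A physical point-spread function
is deliberately out of scope: a linear-in-defocus, monotone blur is
sufficient to exercise every classifier in the package, and monotonicity
is what the sharpness features rely on. Rendering is a pure function of
(configuration, seed): per-object patches are rasterized with ~1 px
anti-aliasing, blurred by the object's own defocus, min-composited onto
the bright background (stains only darken bright-field images), and
finished with a small deterministic additive noise (sd 0.005).

### Desk-scale study conditions

The defaults are fixed once, at one half of the native scanner
resolution, and all tests and the acceptance script run under them:

| quantity | default | why |
|---|---|---|
| pixel size | 0.92 µm (native 0.46 × 2) | keeps tiles small enough to simulate in R |
| slide raster | 4096 × 4096 px | preserves the 16-region geometry |
| cell circle | 2.2 mm diameter | 1/10 of the physical 22 mm circle |
| focus strip | 512 × 64 px | the scanner's wide-and-short line-sensor shape |
| `n_cells` | 500 | areal density of a 30–60k-cell clinical slide at 1/100 area |
| surface range | 21 µm | a typical within-slide height variation (observed slides span ~12–30 µm) |
| dust offset | 40 µm | not published anywhere; free parameter, large enough to be disjoint |
| size threshold | 50 px | the 200 px nucleus rule scaled by (1/2)² |

Because object areas scale with the square of the resolution factor, the
200-pixel native size filter becomes 50 px here, and the 4-megapixel
cluster exclusion becomes 1 Mpx; both remain configurable and the
native-scale values stay the documented reference points.

## Focus-point validity

`classify_focus_point()` is a conjunction of three rules on one strip:

1. **Size** — threshold the grayscale strip at the background level minus
   a small margin (0.05), label connected components, require one object
   of at least the small-nucleus area. The background level is estimated
   per image as the intensity-histogram mode, falling back to a
   configured constant (230/255) when no clear mode exists, since how
   "background areas" are chosen on real slides is not specified
   anywhere.
2. **Edges** — Canny with smoothing σ 1.41 and high threshold 0.07, low
   threshold 0.4 × high (the hysteresis ratio is unspecified upstream,
   so it is a config knob). The threshold is applied to the *absolute*
   Sobel gradient magnitude of the unit-scaled image, not to a
   max-normalized magnitude: max-normalization would rescale the faint
   gradients of a uniformly blurred or blank-noisy strip back above
   threshold and defeat the rule's purpose. At least one edge pixel is
   required.
3. **Color** — convert object pixels to HSV and count, per class, pixels
   inside the class interval (hue may wrap the circle); require ≥ 10 in
   some single class. The published per-class interval values are not
   available, so the defaults are re-derived from the stain chemistry
   (hematoxylin ≈ hue 0.50–0.75 with moderate saturation; pale
   low-saturation cytoplasm; DAB brown ≈ 0.03–0.14; Fast Red wrapping
   0.90–0.05) and are fully user-overridable — the contribution is the
   rule's structure, not its constants. The text ("belonged to one of
   these classes") is read as a per-class threshold; the pooled count is
   also reported in the diagnostics.

Grayscale conversion uses standard luma weights (0.299/0.587/0.114),
which is likewise unspecified upstream.

## Slide sharpness

The slide is tiled 4 × 4. Cells are detected once on a low-resolution
overview (Otsu threshold, connected components, and an HSV test requiring
30% of an object's pixels to be stain-colored — this is what rejects
dust), assigned to regions, and up to 200 per region are sampled. The
overview is rendered at 384 px width: at coarser resolutions neighboring
cells begin to merge into single components and detection recall drops.
Detected objects outside the area bounds (cluster > 1 Mpx at working
scale, or below the 50 px small-cell floor — the nucleus constant reused,
since no explicit number exists for "very small cells") are excluded.

Each sampled 64 px tile yields five features: Canny edge count (same
constants as the validity filter), mean Sobel gradient magnitude, mean
absolute difference to an unsharp-masked copy (σ 1, amount 1), mean
absolute difference to a Gaussian-blurred copy (σ 2), and a
Crété-Roffet-style perceptual blur metric in [0, 1] (re-blur the image
strongly along each axis; if neighboring-pixel variation barely changes,
the image was already blurred). The exact published feature formulas are
not available; these five implementations preserve the documented
separability structure — the first four separate the classes nearly
linearly, the blur metric nonlinearly — and every kernel size is
configurable. A constant tile is defined as all-zero features with blur
metric 1.

Features are z-scored with the training statistics before the SVM. The
upstream description fixes only "RBF kernel with scaling factor sigma of
1", which is scale-sensitive; standardization is what makes σ = 1
meaningful, so it is built into the model object
(`train_sharpness_model()` stores center/scale and the feature
configuration; `e1071::svm` provides the fit with
`gamma = 1/(2σ²) = 0.5`).

Region score = percentage of sampled cells classified in-focus; slide
score = arithmetic mean of region scores over regions with at least one
examined cell. Empty regions are excluded from the mean and never trigger
refocusing — averaging zeros for cell-free glass would punish sparse but
perfectly focused slides. A `strict` mode divides by all 16 regions for
users who want the literal "divided by the total number of regions"
reading. A region is listed out-of-focus when its score falls below the
slide threshold (default 90); no separate per-region cutoff is published,
so the two thresholds coincide by default.

## The scan workflow

`run_workflow()` implements the loop: detect the cell circle (fixed dark
threshold 0.1 on the macro image segments the ThinPrep border marks;
their centroid is the circle centre; diameter is known), place 12 points
on a quasi-uniform sunflower spiral, autofocus and validate, and proceed
to scanning only when *more than five* points are valid — read as ≥ 6,
since the strict wording is repeated twice upstream. Otherwise the point
count escalates by 12 per iteration (capped at 85, the largest observed
operational count) for at most 5 iterations; after a failed attempt the
points are re-set and the whole procedure restarts, at most twice (the
restart clause has no published bound; an unbounded loop is not
acceptable in an autonomous tool). After each scan the slide is scored:
pass ends the session `completed`; "completely out of focus"
(operationalized as score < 30 with ≥ 12 regions below threshold — the
three quality states are named upstream without numeric boundaries) adds
points everywhere and re-scans; otherwise new points are concentrated in
the out-of-focus regions only. Seven scan rounds bound the loop; slides
still failing are `not_scannable`.

The focus map is a thin-plate spline through the valid points' heights:
exact at every data point, reproduces a plane from three coplanar points,
and smooth in between. (A Delaunay piecewise-linear interpolant would do
equally well; no triangulation library is available in the package's
dependency budget, and the TPS solve is a dozen lines of linear algebra.)
Evaluations are clamped to the observed z range of the valid points, so
extrapolation beyond the point hull can never leave the physically
measured height band — with nearest-point behavior recovered naturally
for one or two points.

The virtual scanner's autofocus locks onto objects inside the central
quarter of the strip footprint, mirroring the central contrast window of
a real line-sensor routine; a probe over dust locks the dust plane with
probability proportional to local dust coverage, and a probe with nothing
in its window fails to lock and returns a far-defocused height (whose
strip the filters then reject). This is what makes nearly-empty slides
fail focusing the way real inadequate samples do.

`repeat_scan_cv()` re-runs the whole workflow with identical
configuration and distinct RNG substreams and reports the coefficient of
variation of the final scores, the same reproducibility measurement made
on the physical system.

## Z-profile analysis

`separate_layers()` splits a focus-point height dataset at the largest
gap between consecutive sorted z values, provided the gap exceeds 3× the
pooled within-cluster standard deviation (the physical analysis separated
the layers by visual inspection; the guard keeps single-layer data
intact). The lower cluster — nearer the objective — is dust.
`z_stats()` reports sample (n−1) statistics; `layers_needed()` is
`ceil(range/spacing)` with a minimum of one layer.

## Problem sizes, tolerances, degenerate inputs

* Tests and the acceptance script use the desk-scale defaults above;
  the heaviest computations are an 800 + 800-tile training set with a
  200 + 200 independently seeded test set, 200 ground-truth focus
  strips, and two full workflow runs.
* Determinism: every generator and every stochastic sub-step draws from
  a named substream derived from one seed; identical seeds give
  bit-identical slides, strips and sessions.
* Degenerate inputs: an empty slide renders pure background and scores
  "no-data"; a constant tile has all-zero features and blur metric 1; a
  single focus point yields a constant map; single-class SVM input is an
  error and indistinguishable classes are flagged near chance; zero
  metric denominators yield `NA`, never 0.
* Two published metric values disagree slightly with their own printed
  counts (a PPV printed 98.9 where the counts give 99.0, a specificity
  printed 95.9 where the counts give 96.6); `classification_metrics()`
  always reports the exact quotient and the discrepancy is documented
  rather than reconciled.

## What the simulator does and does not show

The generator reproduces the features the classifiers actually test —
stain-faithful colors, nucleus/cytoplasm geometry at the right pixel
scale, a smooth 3-D surface with realistic peak-to-peak range, a disjoint
gray dust plane, monotone defocus blur. It deliberately omits optical
aberrations, vignetting, sensor noise beyond small additive Gaussian,
JPEG artifacts, overlapping tissue folds, mucus and blood debris.
Passing the synthetic acceptance suite therefore demonstrates that the
*algorithms* are implemented correctly and behave as designed under
controlled conditions; it does not re-establish the published real-slide
accuracies (98.6% on 2,295 real strips, 94.8% on 3,232 real cell images),
whose image data were never deposited.

Known limitations: a strip containing both sharp dust and a strongly
defocused cell can satisfy all three validity rules at once (edges and
size from the dust, color from the blurred cell's residual stain) and
admit a dust height into the focus map — a failure mode of the
conjunction rule itself; the re-scan loop recovers from it, and the
acceptance script reports the measured dust fraction for every run.
Scan timing is not modeled at all: wall-clock performance of the
physical system is hardware-bound and out of scope.
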