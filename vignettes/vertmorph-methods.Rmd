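---
title: "Vertebral morphometry and Genant-rule fracture detection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebral morphometry and Genant-rule fracture detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertmorph)
```

## The problem

Vertebral insufficiency fractures — compression fractures through
osteoporotic bone — are graded on mid-sagittal spine images by how much
height a vertebral body has lost and where: anterior loss (wedge), central
endplate depression (concave/biconcave), or global collapse relative to its
neighbors (crush). The Genant semiquantitative scheme operationalizes this
with three height ratios compared against a healthy population. A fully
automated reading requires a chain of steps, each of which this package
implements behind a small, testable interface:

1. **Standardization** — select the eligible sagittal T2-weighted series,
   keep the central slice, resample to 0.6 × 0.6 mm on a 448 × 320 canvas,
   divide intensities by 2500 and clip to 1 (the informative T2 range for
   separating vertebral body from anulus fibrosus lies below 2500 on the
   12-bit scale).
2. **Segmentation** — a pluggable stage producing a binary vertebral-body
   mask. A faithful U-net description (five encoder blocks of two
   3 × 3-conv/batch-norm/ReLU stacks, filters 32→512, four skip
   connections, Dice loss, Adam at 0.05, batch 16, 100 epochs) is included
   and executable; the test surface uses an *oracle* backend (phantom
   labels, optionally corrupted) so the pipeline is verifiable without
   clinical data or trained weights.
3. **Post-processing** — hole filling, removal of clusters below
   50 mm², and removal of clusters more than 40 mm from the total
   least-squares line through the large-component centroids.
4. **Corner detection** — three strategies (basin-hopping from the
   minimum-area bounding rectangle, boundary-curvature maxima, side-line
   intersections), arbitrated by the overlap (IoU) between the mask and the
   quadrilateral spanned by the four corners.
5. **Morphometry** — anterior, posterior and central heights (AH, PH, CH),
   superior and inferior endplate concavities (SC, IC), and the vertebral
   angle (VA, positive when the endplate chords converge anteriorly).
6. **Classification** — wedge if AH/PH, concave if CH/PH, and crush if the
   overall height relative to adjacent vertebrae falls more than three
   standard deviations below its healthy-population mean (strict
   inequality); precedence crush > wedge > concave when several rules fire.
7. **Agreement and diagnostic statistics** — ICC (two-way forms), Cohen's
   kappa, Bland-Altman limits of agreement, and
   sensitivity/specificity/accuracy with exact binomial intervals; two
   estimates differ significantly only if their 95% CIs are disjoint.

## The synthetic phantom: what it is and is not

`generate_phantom()` renders a stack of vertebral bodies as quadrilaterals
whose endplates carry circular-arc depressions, over disc gaps, with
T2-like contrast and additive Gaussian noise, and returns *analytic* ground
truth (corners, morphometry, fracture status) computed from the generating
geometry, never from the raster.

Defaults describe a healthy adult lumbar column: 27 mm body height, 33 mm
width, 9 mm disc gaps, 1 mm baseline endplate concavity, 0.6 mm pixels,
per-vertebra tilt within ±15°. Deformities are parameterized by a severity
in [0, 1]:

* **wedge** — the anterosuperior corner descends so AH becomes
  `1 − 0.6·severity` of baseline (60% maximal anterior loss);
* **concave** — both endplate depressions deepen linearly from 1 mm to
  6 mm at severity 1 (a biconcave, "fish" vertebra). Real concave
  deformities depress the central endplate while the cortical rim stays
  near-perpendicular, so the arc spans the central 80% of the endplate
  with flat shoulders; a full-width arc would create an acute corner tip
  that neither a 0.6 mm grid nor a reader could localize.
* **crush** — both superior corners descend by the same 60%-maximal
  factor.

The maximal-loss parameters are chosen so severity 1 exceeds any plausible
3-SD Genant threshold by a wide margin. Truth fracture status is obtained
by running the package's own classifier on the analytic morphometry with
the shipped default norms, which makes truth consistent with the
generating thresholds by construction. Rendering uses area sampling (a
pixel is foreground when at least half its area is inside the polygon), a
partial-volume-like criterion that also preserves thin corner tips.

The phantom deliberately omits: 3-D anatomy and through-plane effects,
coil/bias fields, osteophytes, Schmorl nodes, degenerative endplate
irregularity, scoliosis, and the intensity statistics of real marrow. A
green test therefore establishes that the *geometry and decision chain*
are correct at clinical scale and realistic noise — not that the pipeline
reaches any particular accuracy on patient MRI.

## Corner detection: objectives, ties and sub-pixel choices

The arbitration between strategies uses IoU, as the deployed system did.
Two implementation findings shaped the internals:

* **Basin-hopping objective.** With corner candidates restricted to the
  mask border (which the exhaustive-search oracle also assumes), a pure
  IoU objective is maximized, on a concave endplate, by corners *inside*
  the depression — cutting the depression out of the union outweighs the
  lost covered area, biasing every height low by up to several mm. The
  basin-hopping stage therefore maximizes the covered mask fraction
  |mask ∩ quad| / |mask| (with an infinitesimal quad-area tie-break). On
  convex bodies — every oracle-equivalence toy — this is *identical* to
  IoU, because a border-cornered quadrilateral never covers background
  there. The selector itself still scores all strategies by IoU.
* **Landmark sharpening and pixel extent.** On tilted, stair-stepped
  borders all overlap objectives are flat over the last one or two pixels
  of a corner tip, so each corner may move within ±2 border pixels if that
  enlarges the quad (the anatomical corner is the outermost consistent
  landmark). Finally, a border pixel's *centre* underestimates the
  physical corner by half a pixel per axis; landmarks are reported at the
  pixel's outer corner (half-pixel outward along the image diagonal).
  On an axis-aligned rectangle the landmarks are then exactly the
  rectangle's geometric corners, and systematic height bias vanishes.

The curvature strategy treats the traced border as the concave hull of
the segmentation boundary, resampled at `hull_alpha` (default 3 × pixel
spacing) and scored by the k-cosine measure over a 7-vertex window; the
four maxima must be separated by at least one eighth of the perimeter, and
each coarse peak is re-localized on the full-resolution border. The
line-fit strategy partitions border pixels by the nearest side of the
minimum-area bounding rectangle and fits total-least-squares lines, using
only points on (within half a pixel of) the convex hull so a deep
depression contributes its support line — the line a reader would draw —
rather than a mid-depth chord; intersections are snapped to the border.

## Measurement definitions

Heights are corner-to-corner distances (AH anterior, PH posterior).
Concavities are maximum perpendicular depressions of the endplate border
path below/above the corresponding corner chord — perpendicular to the
chord, not image-vertical, so the measures are tilt-invariant. The central
height is read along the perpendicular of the mean chord direction through
the mid-chord point (configurable fraction, default 0.5); truth and
measurement share one implementation of this construction. The vertebral
angle is the signed angle between the endplate chords, positive when they
converge anteriorly.

## Classification

All three Genant ratios use strict `ratio < mean − 3·SD`. "Overall height"
for the crush rule is `mean(AH, CH, PH)` (configurable); the neighbors are
the cranially and caudally adjacent measured vertebrae, and the rule is
skipped (and recorded as skipped in the audit trail) when no neighbor is
available. The shipped default norms (anterior 0.96 ± 0.04, middle
0.91 ± 0.045, neighbor 1.00 ± 0.05) are placeholders in the spirit of
published morphometry tables and are **not clinically validated**; the
reference population used by the original system was never published, so
any real use must supply its own `reference_norms()`. By default only
L1–L5 receive fracture calls; neighbors outside that range still
contribute to the crush rule.

## Statistics

The ICC defaults to the two-way random-effects, absolute-agreement,
single-measure form, computed from the balanced two-way ANOVA mean
squares, with the standard F-based confidence construction and Koo
interpretation bands; a consistency form is available. Kappa uses
marginal-product expected agreement with Landis–Koch bands. Bland-Altman
reports the mean difference (first argument minus second) with limits of
agreement ±1.96 SD. Diagnostic proportions use Clopper-Pearson intervals
by default (Wilson optional): recomputing the published multicenter
validation table from its contingency counts reproduces all 39 point
estimates exactly at three decimals, and the whole-cohort interval bounds
to within 0.001 (the original CI software is unnamed).

## Numerical and degenerate-input choices

* Resampling: bilinear for intensities, nearest-neighbour for label masks;
  canvas fitting by symmetric centre crop/pad. Unit-range inputs are
  rescaled by 2500 before the divide-and-clip so re-standardizing a
  standard slice is a no-op up to interpolation round-off.
* 0-based pixel indices map to mm as `index × spacing`; polygon membership
  is pixel-centre-in-polygon (even-odd rule) except the phantom renderer's
  area sampling.
* Dice of two empty masks is defined as 1. ICC with zero between-subject
  variance, kappa with unanimous constant raters, and classification
  without norms raise explicit errors rather than returning defaults.
* Basin-hopping: zero-temperature acceptance, iteration cap 50, default
  seed 0; deterministic for a fixed seed, as is the whole pipeline.
* The U-net implementation normalizes over the spatial axes of each
  instance (batch-of-one batch-norm semantics), which keeps inference
  deterministic without running statistics; gradients are validated
  against finite differences in the test suite.

## Desk-scale stand-ins for clinical results

The published clinical numbers (median Dice 0.968 on the study's test set;
reader-agreement ICCs; sensitivity 0.941 / specificity 0.969 / accuracy
0.962 on 1000 vertebrae) cannot be reproduced here: the images and trained
weights were never released. The test suite replaces them with property
targets — exhaustive-search corner equivalence on toy masks, phantom
parameter recovery within 1.2 mm / 2°, statistics oracles, an end-to-end
phantom sensitivity/specificity ≥ 0.9 target, and a training smoke test in
which a width-reduced U-net (filters from 8) trained for ≤ 5 epochs on 32
coarse phantom slices exceeds Dice 0.8 on held-out phantoms (the rasters
are 96 × 64 at 3 mm to fit a single-CPU budget). The
diagnostic-statistics layer *is* checked against the published tables,
which are printed data and fully recomputable.

## Known limitations

* The phantom's realism gap (above) means segmentation difficulty is not
  representative; the oracle backend plus corruption model tests the
  post-processing contract, not segmentation accuracy.
* Reference norms are placeholders; fracture calls with the defaults are
  for testing and demonstration only.
* DICOM parsing is out of scope (no DICOM reader exists in the supported
  dependency set); series selection operates on a descriptor table, and
  images enter as NIfTI or matrices. The bundled NIfTI reader/writer
  covers the single-file subset this package writes.
* No Genant severity grading (mild/moderate/severe), fracture-age
  assessment, or benign-vs-malignant discrimination.
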