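---
title: "Hybrid circle detection and wear measurement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid circle detection and wear measurement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipwear)
```

## The measurement problem

After total hip arthroplasty (THA), the polyethylene liner between the
prosthetic femoral head and the acetabular cup wears down over years. On an
anteroposterior (AP) radiograph both components project as nearly concentric
circles — the head as a bright disc, the cup as a bright annular rim — and
the classical planar wear measures reduce to circle geometry: how far the
head center has migrated toward the cup center (medial wear), how much the
superior joint space has narrowed (superior wear), and the Euclidean
resultant of the two. The measurement problem is therefore a circle-recovery
problem: estimate the centers and radii of two circles, per image, robustly
enough that differences of a few pixels between serial radiographs are
meaningful.

hipwear implements the geometric half of a hybrid detection pipeline. An
external object detector (or any other source, including manual annotation)
supplies a coarse region of interest (ROI); everything anatomical —
edge extraction, radial refinement, robust fitting, plausibility filtering,
and the wear arithmetic — is deterministic image analysis implemented here.
The package deliberately does not train or ship a detector: ROIs enter
through a plain provider interface (`oracle_roi_provider()` for synthetic
ground truth, `read_detections()` for external detector output), which keeps
the geometric pipeline testable in isolation.

## Annotation geometry

Circles are annotated in a resolution-independent text form, one line per
structure: `cls x y r` with class 0 = femoral head, class 1 = cup. For an
image of width $W$ and height $H$,

$$x = \frac{c_x}{W}, \qquad y = \frac{c_y}{H}, \qquad
  r = \frac{r_\mathrm{px}}{(W+H)/2}.$$

The radius denominator is the mean image dimension; this is applied
literally for all aspect ratios. The equivalent detector-style bounding box
keeps the circle center and uses normalized extents
$w = r\,(1 + H/W)$, $h = r\,(1 + W/H)$, so that in pixel space the box side
equals the circle diameter exactly in both axes. `box_to_circle_proposal()`
inverts this construction: the initial radius of an ROI-derived circle
proposal is *half* the average box extent, which makes proposal and
circumscription mutually consistent (a box of a circle proposes exactly that
circle back).

Normalized fit errors use the same scale: center error is the Euclidean
center distance divided by $(W+H)/2$, radius error is $|\Delta r|$ divided
by $(W+H)/2$. A "2% tolerance" therefore means 2% of the mean image
dimension.

## Edge extraction

Each ROI crop is enhanced by CLAHE (clip limit 2.0, 8×8 tiles), an
edge-preserving bilateral filter (9 px window, range and spatial sigma 75),
and unsharp masking (amount 1.0, sigma 1.5 px). Canny hysteresis thresholds
are set adaptively from the median gray level $v$ of the enhanced crop:

$$T_\mathrm{low} = \max(0, (1-\sigma)\,v), \qquad
  T_\mathrm{high} = \min(255, (1+\sigma)\,v), \qquad \sigma = 0.33.$$

This is the standard auto-Canny form; thresholds are clamped to the 8-bit
range. The refinement stages consume a *combined* per-pixel response

$$\mathrm{combined} = w_c \cdot \mathrm{canny} +
  w_g \cdot \frac{|\nabla I|}{\max |\nabla I|},$$

with default weights $(0.5, 0.5)$: the binary Canny mask contributes
localization confidence, the normalized gradient magnitude contributes a
continuous sub-pixel profile. The Canny chain itself (Sobel gradients,
sector-quantized non-maximum suppression, hysteresis linking) is implemented
in the package; hysteresis uses connected components of the 3×3-dilated weak
mask, which realizes 8-connected linking with the side effect of also
bridging 1-pixel gaps — harmless for edge validation, and irrelevant to
sub-pixel localization, which comes from the gradient term.

Note one measurement-scale subtlety established while testing the contrast
property: the bilateral range sigma (75 gray levels) is larger than typical
rim steps (20–125 levels), so measured immediately at the boundary (±2 px)
the filter smooths part of the step that CLAHE gained. Measured just beyond
the filter window (±4 px), enhancement strictly increases rim-adjacent
contrast. The enhancement chain is configured for edge *detectability* at
the gradient-operator scale, not for preserving raw adjacent-pixel
differences.

## Edge-Snap radial refinement

`edge_snap()` refines a circle's radius only. It samples the combined
response along `n_angles` (360) rays from the current center, at radii
within an annulus of half-width `annulus_frac` (0.20 femoral, 0.10 cup
candidates) around the current radius, step 0.25 px, and takes the
per-angle radius of maximal response. Angles whose peak response is below a
noise floor (0.30, calibrated to combined weights summing to 1) are
discarded; if fewer than `min_support_frac` (0.10) of the angles survive,
the input radius is returned unchanged with the support fraction reported.
Surviving radii are pooled by a weighted median (weights = peak responses,
radius ties resolved downward) — robust to up to half the angles being
contaminated by occlusion, screws, or a neighboring boundary. Center
refinement is deliberately left to RANSAC (femoral) and the candidate grid
(cup): a radial search from a fixed center cannot separate a center offset
from a radius change, so the division of labor avoids a poorly conditioned
joint update.

## RANSAC fitting

High-response Canny pixels in a thin ring around the snapped radius
(`ring_frac` 0.10 femoral / 0.08 cup, response quantile 0.5 / 0.6) are
passed to `ransac_circle()`: circle hypotheses from point triplets, scored
by inlier count with ties broken by lower mean inlier residual; an inlier is
a point within `inlier_tol` = 2 px of the hypothesized circle. When the
number of distinct triplets is at most `n_iter` (500), all triplets are
enumerated — the search is then exhaustive and exactly matches a brute-force
oracle, which is how the tests verify it. The winning hypothesis is polished
by a Kåsa algebraic least-squares fit on its inliers: closed-form,
deterministic, and exact on noise-free circular data, which is all a RANSAC
polish step needs (an iterative geometric fit would change results by far
less than the imaging noise). Degenerate triplets are detected by a triangle
area below $10^{-9}\times$ the squared point spread.

A fitted radius that jumps more than `radius_jump_frac` (0.25) of the
snapped radius is rejected in favor of the snapped circle — a cheap guard
against fits through short, nearly straight arc fragments.

## Cup candidate search and composite scoring

The cup rim is usually only partially visible, so the cup is refined by
search rather than by a single fit. A deterministic grid around the ROI
proposal (5×5 center shifts within ±8% of the radius, 7 radius scales in
[0.85, 1.15]) is snapped per candidate, deduplicated, optionally
RANSAC-polished, and scored by six criteria, each in [0, 1]:

* **edge support** — among Canny pixels in a wide band around the candidate
  radius, the fraction within a narrow tolerance of it (a sharpness ratio;
  deleting supporting pixels can only lower it);
* **angular coverage** — fraction of 72 angular bins containing supporting
  points;
* **longest arc** — longest contiguous run of covered bins (reported in
  radians, normalized by $2\pi$ in the total);
* **gradient alignment** — mean agreement between the local gradient
  direction and the *inward* circle normal. The polarity matters: a metal
  component is brighter than its surroundings, so at the true outer contour
  the intensity gradient points inward. The inner liner boundary has the
  opposite polarity, and an unsigned alignment cannot tell the two apart —
  with saturated contrast the snap's lower-radius tie-break then locks onto
  the inner boundary systematically (observed as a fitted radius short by
  exactly the rim width on ~17% of test phantoms before the polarity term
  was introduced);
* **center proximity** — 1 minus the distance to the ROI center over half
  the ROI diagonal;
* **outside fraction** — fraction of supporting points outside the femoral
  circle, penalizing candidates that cut through the head.

The total is the weighted mean, default uniform weights (1/6 each, exposed
in configuration). Absolute totals are configuration-dependent; tests
therefore assert orderings and component bounds, not specific totals.

## Anatomical filtering

A femoral/cup pair is accepted only if: the cup radius strictly exceeds the
femoral radius; the head sits strictly inside the cup with a joint-space
clearance of at least `min_gap` (1 px) — i.e.
$r_\mathrm{cup} - r_\mathrm{fem} - \|c_\mathrm{cup}-c_\mathrm{fem}\| \ge
\mathrm{min\_gap}$, which encodes both non-intersection and the liner
thickness; the cup center lies inside the ROI (the practical form of
rejecting candidates drifting toward the contralateral hip, which would
require laterality information the pipeline does not have); and the Canny
edge density in a ±2 px ring band around each circle is at least
`min_edge_density` (0.10 of angular positions), discarding noise-driven
solutions. Every violated rule is reported by name in the filter's reasons,
and `fit_prosthesis()` re-checks the final pair before returning — a fit
that does not pass cannot be returned.

## Hough fallback

When no candidate passes, or the best composite total is below the fallback
threshold (0.35), a circular Hough transform is run. Two design choices
here:

* **Sensitized edge map.** The fallback exists because edge contrast within
  the ROI was insufficient; rerunning the Hough transform on the same edge
  map that starved the primary path would inherit the same empty evidence.
  The fallback therefore recomputes the Canny map with the thresholds scaled
  by `relax` (0.3) and votes on that. Both the Hough candidates *and* the
  incumbent are re-scored on the sensitized map, so the strictly-greater
  replacement rule compares like with like.
* **Masked voting.** Edge pixels inside the already-fitted femoral circle
  (plus the minimum gap) do not vote: the cup must surround the head, and
  the dense head boundary otherwise floods the accumulator at the small end
  of the radius range with defocused votes.

The accumulator is three-dimensional over (center, radius), radius step 1
px; each edge pixel casts two votes per radius, along both senses of its
gradient direction (rim polarity is unknown to the voter). Peaks are
extracted by non-maximum suppression that treats concentric circles of
different radii as distinct (suppression requires both a close center and a
close radius — the head and cup are nearly concentric, and center-only
suppression would delete one of them). A Hough candidate replaces the
incumbent only when strictly higher-scoring; the method field of the result
records which path produced the fit, making the fallback decision auditable.

## Wear computation

With PRE and POST geometries fitted, the wear quantities are pure
arithmetic. The scale factor

$$sf = \frac{r_\mathrm{fem,PRE}}{r_\mathrm{fem,POST}}$$

exploits the fact that the physical head radius cannot change between
examinations, so the radius ratio absorbs any difference in magnification or
pixel spacing; the PRE radiograph is the reference scale. Medial wear is
$\Delta d = d_\mathrm{POST}\,sf - d_\mathrm{PRE}$ with $d$ the center-to-center
distance; superior wear is $\Delta g = g_\mathrm{POST}\,sf - g_\mathrm{PRE}$
with $g$ the distance between the superior points ($y$-top = center $y$
minus radius, in the y-down image convention); the resultant is
$\Delta_\mathrm{total} = \sqrt{\Delta d^2 + \Delta g^2}$. Scaling every POST
coordinate and radius by any $k > 0$ leaves all three unchanged — the
invariance is exact by construction and is asserted to $10^{-9}$ in the
tests.

Two sign conventions were open and are resolved as follows. The superior gap
is the *absolute* difference of the two superior points: the printed
formulas are signed, but the published example values are positive and the
absolute value makes the result independent of the y-axis orientation.
$\Delta d$ and $\Delta g$ themselves remain signed (a head moving away from
the cup center yields a negative medial component), and only the resultant
is non-negative. The center-to-center distance is directionless, so the
medial/lateral direction of migration is not recoverable from it and no
direction label is attached.

When a pixel-per-millimetre magnification factor $M$ is supplied, the
resultant is also reported as $\Delta_\mathrm{total}/M$ millimetres; no
attempt is made to read calibration from image metadata.

## The phantom generator

`generate_phantom()` renders the geometry the pipeline is built for, with
known ground truth: a background level (60), a joint-space interior at
background + `gap_contrast` (50), a femoral disc at interior +
`head_contrast` (90), and a cup rim annulus of width `rim_width` (6 px)
ending exactly at the cup radius, at background + `rim_contrast` (125). With
these defaults the outer rim boundary carries the strongest radial step
(125 gray levels, vs 75 at the inner rim and 90 at the head boundary), so
the per-angle edge maximum sits at the annotated cup radius — verified
analytically in the tests. Boundaries are anti-aliased by linear coverage
over one pixel, which is what makes sub-pixel recovery measurable.
Degradations: seeded additive Gaussian noise (clipped to [0, 255]), rim
deletion over configurable angular arcs, and bright line segments emulating
screws.

`sample_phantom_spec()` draws study conditions: head radius 40–58 px on a
320×320 crop, cup/head radius ratio 1.6–1.85 (a 28–36 mm head in a
50–58 mm cup, the dominant THA configurations), near-concentric centers
(cup offset ≤ 3 px), noise sigma 0–8, occlusion up to 60°, up to two screw
lines. The recovery suite runs 30 such phantoms with ROI boxes jittered by
2% — a stand-in for detector error — and requires every normalized center
and radius error to stay within 2%; the measured errors are one to two
orders of magnitude below that bound. `generate_pre_post_pair()` renders a
PRE/POST pair with a known head shift and a POST magnification change, plus
the analytically expected wear report, exercising the full
fit-then-measure round trip.

What the phantom does *not* emulate: pelvic bone texture, overlapping
anatomy, projection tilt (the rim is circular, never elliptical), beam
scatter, or implant-specific silhouettes. Passing the synthetic suite
demonstrates that the geometric machinery is correct and robust to the
modeled degradations; it does not certify clinical accuracy, and
dataset-level detector metrics (mAP, per-class precision/recall on
radiographs) are explicitly out of reach without the clinical images and
trained weights. The detection-metrics module is therefore validated by
oracle equivalence (exhaustive threshold enumeration, brute-force matching)
on constructed rankings instead.

## Numerical and scale choices

* Problem sizes in the shipped tests and the acceptance script — 320×320
  phantoms, 30-phantom recovery runs, ≤12-point exhaustive RANSAC
  instances, ≤64×64 brute-force Hough maps — were chosen so the full
  verification cycle completes in a couple of minutes on one core while
  still exercising every code path; the recovery bound (2%) is far above
  the measured errors, so the margin is not scale-sensitive.
* All randomness (noise, screws, jitter, RANSAC triplets) flows through
  explicit integer seeds, and seeded helpers restore the caller's RNG
  state; identical inputs and seeds give bit-identical results, which the
  tests assert.
* The worked-example reproduction keeps 6-decimal agreement where the
  published inputs support it; one published table is internally
  inconsistent at the $7\times10^{-6}$ level between its scaled cells and
  its own printed inputs, so that table is checked to $10^{-5}$ absolute.
* Collinearity tolerance ($10^{-9}\times$ squared spread), the Edge-Snap
  noise floor (0.30), the fallback threshold (0.35) and relax factor (0.3)
  are engineering constants exposed in `hip_config()`; none were derived
  from data, and the property tests are designed to hold with margin rather
  than at the constants' edges.

## Known limitations

* The cup rim is modeled as a circle; a tilted cup projects an ellipse, and
  the systematic radius bias this induces is not corrected.
* Wear is planar (2D); out-of-plane penetration is invisible in a single AP
  view.
* The ROI contract assumes one implant per ROI; bilateral hips need two
  ROIs.
* Millimetre conversion requires a user-supplied magnification factor.
* The anatomical filter's ROI-containment rule is only as good as the ROI;
  a detector box centered on the wrong hip will not be caught.
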