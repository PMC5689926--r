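---
title: "Predicting dosimetric eligibility from PTV–OAR overlap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dosimetric eligibility from PTV-OAR overlap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlaptriage)
```

## The problem and the model

Hypofractionated prostate radiotherapy (6000 cGy in 20 fractions) relies on
strict rectal- and bladder-wall dose constraints; a patient whose plan
cannot meet the *accepted* constraint set is *dosimetrically ineligible*
and must fall back to conventional fractionation. Ineligibility is an
anatomical fate more than a planning failure: the wall D30 constraints cap
the dose to 30% of each wall, so once the PTV overlaps much more than ~30%
of a wall, coverage and constraint cannot coexist.

The package's model is deliberately minimal. With `f_BW` and `f_RW` the
fractional overlaps of bladder wall and rectal wall with the PTV, the
combined metric is

$$ m = \sqrt{f_{BW}^2 + f_{RW}^2}, $$

the radius of the patient's point in the first quadrant of the
$(f_{BW}, f_{RW})$ plane. Classification is a single inclusive cutoff —
*ineligible iff* $m \ge t$ — and the decision-support zones are two
quarter-circle arcs: feasible strictly inside the inner radius, not
feasible strictly outside the outer radius, uncertain between (arcs
included). The model assumes (i) both overlaps are measured on the same
co-registered grid as the PTV, (ii) eligibility is driven by wall overlap
rather than by, say, small-bowel dose or plan robustness, and (iii) the
local planning and contouring practice resembles the one under which any
shipped or refitted cutoffs were learned.

## Geometry

Structures are 3D logical voxel grids with physical spacing (mm), origin,
and explicit anatomical axis labels (`R/L`, `A/P`, `S/I` per grid axis).
Directional semantics are always resolved through the labels, never from
array order, so a posteriorly-reduced margin cannot silently flip sides.

* **Voxel model.** A voxel belongs to a structure iff its *centre*
  satisfies the defining predicate; there are no partial volumes, and every
  boundary predicate is closed (`<=`). This makes each operation equal, by
  construction, to a brute-force evaluation over voxel centres, which is
  exactly how the test suite checks it.
* **Margin expansion.** The CTV→PTV expansion uses a piecewise-ellipsoidal
  kernel: displacement $d$ is inside the margin iff
  $\sum_i (d_i/m_i)^2 \le 1$, where each component picks the margin of the
  half-axis matching its sign. For isotropic margins this reduces to a
  ball; it is smooth across direction changes, unlike a box kernel. The
  default is the protocol margin, 10 mm everywhere and 7 mm posteriorly.
  Dilation (and the erosion inside wall extraction) is computed as an FFT
  convolution of the mask with the kernel's indicator, thresholded at a
  half-count; with counts being integers the floating-point slack (~1e-9)
  cannot change a verdict.
* **Wall extraction.** `wall_from_solid()` subtracts the erosion by a
  physical-radius ball. The 3 mm default thickness is a conventional
  contouring choice, configurable because wall definitions vary between
  centres; synthetic walls are a stand-in, not a claim about how any trial
  contoured them.
* **Rasterization.** Contour slices map to the nearest voxel plane; points
  are tested by even-odd crossing count with points exactly on an edge
  counted inside, matching the closed-boundary convention. Self-touching
  or overlapping polygons on one slice are OR-ed.

## Classifier, cross-validation, zones

* **Candidate cutoffs** are the midpoints between consecutive distinct
  feature values plus one sentinel below the minimum and one above the
  maximum: every achievable labelling of the cohort by the rule appears
  exactly once. The fit maximizes training accuracy; among ties the
  *smallest* cutoff is returned, which flags more patients as ineligible —
  the conservative direction for a triage tool, where a premature consult
  costs less than a wasted planning attempt. The optimization target
  (plain accuracy) is itself a design choice; sensitivity-weighted targets
  would shift cutoffs downward.
* **Rates** use eligible as the positive class: sensitivity is the correct
  detection of eligible patients, specificity of ineligible ones.
* **Cross-validation** is true stratified two-fold: each class is randomly
  halved, both folds serve once as train and once as test per repetition,
  and mean/sd aggregate over all `2 * n_repetitions` fold evaluations (not
  over per-repetition averages) — the simplest unit to audit. For odd
  class counts the extra patient lands in either fold with probability
  one half. All draws flow through R's generator scoped by
  `withr::with_seed`, so a report is bitwise reproducible from its seed.
* **Zones** derive from a labelled cohort as `r_inner` = the smallest
  metric among ineligible patients and `r_outer` = the largest among
  eligible ones; the feasible and red zones are therefore pure on the
  training cohort by construction. If a cohort is perfectly separated the
  raw radii invert; they are swapped and flagged, keeping the three-zone
  contract total with an empty uncertain band. Boundary metrics classify
  as *uncertain*: where a convention had to be picked, it leans toward
  caution. The
  shipped radii (0.274, 0.305) are defaults from a published 150-patient
  institutional cohort; they should be refit locally, since optimal
  cutoffs depend on planning expertise and contouring philosophy.

## Constraint checking

Dx is read off the cumulative DVH as the largest dose at which the
fractional volume still reaches `x/100`, with piecewise-linear
interpolation between tabulated points (the standard DVH convention; a
nearest-bin rule would differ by at most one bin width). Wall and femur
limits are upper bounds; the CTV/PTV D99 limits are coverage minima —
the table prints no directions, but a D99 floor at prescription level can
only be coverage. Exact equality passes in both directions ("meet the
constraints" read inclusively). The stricter *preferred* set ships as a
named alternative but never drives labelling.

## What the synthetic generators emulate

`generate_cohort()` draws `f_BW ~ 0.42·Beta(1.8, 4.2)` and
`f_RW ~ 0.42·Beta(2.2, 2.9)` — bounded, unimodal, right-skewed — and
labels patients by a latent-noise rule `eligible = (m + ε) < t*` with
`t* = 0.28`, `ε ~ N(0, 0.02)`. The defaults were calibrated once so the
realized ineligible fraction averages the 29.3% target, the metric spans
roughly 0.05–0.45, and the rectal-wall overlap is both larger and more
informative than the bladder-wall overlap while PTV volume stays a weak
predictor (its log-normal location shifts only from 193 cc to 204 cc
between classes). σ interpolates between perfectly separable (σ = 0,
labels exactly threshold-determined) and noisy cohorts.

`generate_anatomy()` builds an idealized pelvis — ellipsoidal prostate,
posterior rectal tube, anterior-superior bladder sphere — and returns
analytic volumes for oracle checks. `generate_dvhs()` links wall D30 to
overlap through a logistic curve crossing the 4710 cGy limit near overlap
0.30 (the geometric heuristic above), with D50 tied to D30 by the
3790/4710 limit ratio so both wall constraints fail together. Chaining
anatomy → overlap → DVH → constraint check yields cohorts whose labels
arise from geometry, which is what the end-to-end tests exercise.

What the generators do *not* emulate: real contouring variability,
deformable anatomy, correlated bladder/rectum filling states, dose-grid
physics, or the published cohort's actual feature distributions (figure
quartiles were never read off). Passing tests therefore demonstrate the
*machinery* — geometry, fitting, validation, zone semantics — under a
mechanism the method assumes, not clinical performance on real patients.

Two quantitative caveats are worth naming. First, with a ~70% eligible
cohort any weak feature's cross-validated accuracy floats near the
majority-class floor (~70%), so single-feature accuracies on synthetic
cohorts sit above the published weak-feature values even when the ranking
is preserved. Second, the generator's weak PTV-volume shift means a
rank-sum test on PTV volume is under-powered at n = 150; the published
cohort reported a significant difference alongside poor predictive value,
a combination our simpler label mechanism does not reproduce exactly.

## Numerical and size choices

Degenerate inputs fail loudly with typed conditions: empty structures,
non-co-registered grids, single-class cohorts, classes too small to
stratify, malformed DVHs, out-of-extent contours. Overlap features outside
[0, 1] are domain errors, not warnings.

Test problem sizes are the package's own choices for a thorough but
fast-running suite: brute-force geometry oracles on grids up to 40³ with
sparse structures; anatomy at 2–3 mm spacing (the end-to-end pipeline test
runs 48 jittered patients at 3 mm); cross-validation properties at 10–200
repetitions with the full 1000-repetition protocol exercised by the
acceptance script. The sphere-lens overlap check uses 1 mm spacing, where
the voxelized fraction sits within 3% of the closed-form spherical-cap
ratio (1.5% at 0.5 mm).

## Limitations

Eligibility here means the accepted constraint set only; reasons outside
it (small bowel, robustness, implant artefacts) are invisible to the
metric. The shipped radii encode one centre's practice. Masks must be
axis-aligned and co-registered; there is no resampling, registration or
auto-contouring. DICOM-RT import is out of scope — structures arrive as
NIfTI/NRRD masks or the contour-JSON dialect.
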