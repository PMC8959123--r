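---
title: "Hip morphometry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hip morphometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmorph)
```

# The measurement model

All geometry lives in image coordinates: `x` grows rightward along columns,
`y` grows downward along rows, pixels are 0-based, and "superior" means
smaller `y`. This matches the raster order of DICOM and PNG, so landmark
files can be overlaid on images without any axis flip.

The pelvis supplies its own reference frame. Hilgenreiner's line runs
through the two tri-radiate cartilage centers (Y); every index is an angle
or a length ratio *relative to that line*, which makes the whole
measurement set invariant under in-plane rigid motion of the radiograph.
Internally each computation rotates its points into the
*Hilgenreiner-horizontal frame*; the line's direction is canonicalized to a
non-negative `x` component so the frame preserves the image's left/right
orientation for rotations below 90°.

Laterality is never inferred from pixel positions. Each hip stores
`lateral_sign`, the sign of the image-`x` direction pointing away from the
body midline (+1 for the patient-left hip on a conventionally displayed AP
film). Display conventions vary across viewers; an explicit sign makes the
geometry correct under either convention and makes mirror symmetry exact:
reflecting a landmark set about the midline (and flipping the signs) swaps
the left/right measurements.

## Indices

* **Acetabular index** — angle between the roof segment Y→E and
  Hilgenreiner's line, via `atan2` in the horizontal frame. Signed positive
  when E is superior to Y's level, so normal hips read positive (roughly
  10–35° in the age range of interest).
* **CE angle** — angle at C between the superior perpendicular and the ray
  C→E, positive when E is lateral of the perpendicular. A laterally
  displaced head therefore reads small or negative.
* **Acetabular head index** — with the head modeled as a circle of radius
  `r` around C, coverage runs from the *medial circle edge* (C shifted
  medially by `r`) to E's projection on Hilgenreiner's line, as a
  percentage of the head width `2r`. The medial boundary of the head is
  taken as the circle edge rather than a bony contour because the circle is
  what every radius source (mask area, bounding box, generator) actually
  provides; the value is deliberately not clipped to [0, 100], so frank
  dislocations read negative and over-coverage reads above 100.

Angles are returned in degrees; when `pixel_spacing_mm` is present, lengths
are additionally reported in mm, and no angle changes (angles are
scale-free by construction, a property the test suite asserts).

## Grading rules

Both graders operate in the horizontal frame with two signed coordinates:
`l` (positive lateral of the Perkin line) and `s` (positive superior).

**IHDI** uses the position of H relative to the Hilgenreiner line (H-line),
Perkin line (P-line), and the 45° inferolateral diagonal (D-line) from the
H–P junction (the projection of E onto the H-line): grade I at-or-medial to
the P-line, II lateral of it but at-or-medial to the D-line, III lateral of
the D-line but at-or-inferior to the H-line, IV superior to the H-line.

**Tönnis** compares C with the P-line and the rim level: grade 1
at-or-medial to the P-line, otherwise 2/3/4 for inferior to / within /
superior to the *rim band*. The band is the horizontal strip of half-width
`head_radius` centered on E's superior–inferior level. The clinical rule
compares a finite-sized ossific nucleus against the rim level; the head
radius is the only size scale available, so it sets the band width. Whether
published automated systems use this nucleus-quadrant variant or a pure
head-center rule is generally not reported; this package documents its
variant rather than asserting equivalence to any other.

Ties ("exactly on a line") resolve toward the **lower** grade and are
recorded in `boundary_flags` (`on_perkin`, `on_dline`, `on_hline`,
`rim_band`) so borderline calls are auditable downstream. The equality
tolerance for flagging is 1e-9 px. Both graders are total (every finite
point gets exactly one grade) and monotone: moving H or C laterally or
superiorly never decreases the grade. The test suite checks both properties
against brute-force classifiers written independently from projections in
raw image coordinates.

## Shenton's line

Clinically this is a gestalt judgment; here it is an explicit geometric
rule so it can be tested without trained models, and reports should treat
it as a proxy. A circle is fitted to the pubic arc by algebraic least
squares (Kåsa fit, a linear solve); the line is *intact* when the largest
absolute radial residual of the neck-arc points is at most `tol` px
(default 5 px, the same order as detector landmark error). A numerically
collinear pubic arc makes the fit singular and yields *indeterminate*.
The other two qualitative judgments of a full reading (rim sharpness,
sourcil integrity) are annotation pass-throughs, never computed.

# The detection gate

Keypoint detectors produce plausible-looking femoral-head centers even when
no ossific nucleus is visible. The gate removes C on any side lacking a
femoral-head segmentation ROI with confidence at or above 0.5 (the
threshold is configurable; published pipelines rarely state theirs). The
gate never adds points, never touches E/Y/H, and is idempotent. Gating is
per-side by default — a missing left ROI should not discard a good right
C — with a `"global"` mode that wipes C bilaterally, since some pipeline
descriptions are ambiguous between the two readings. Downstream, an absent
C propagates to absent CE angle, AHI and Tönnis grade; IHDI remains
available from H, which is precisely its clinical role.

The head radius feeding AHI and Tönnis comes from the ROI: the
equivalent-circle radius `sqrt(mask_area / pi)` when a mask area is known,
else a quarter of the mean bounding-box side.

# Preprocessing

Model-space normalization resizes onto a 1333×800 canvas with
`scale = min(1333/w, 800/h)` (bilinear interpolation), padding the shorter
dimension with zeros. The padding is split equally (floor on the top/left
side of an odd remainder) and the full transform — scale, pads, sizes — is
recorded in a `canvas_transform`, so either padding convention is
recoverable and the original↔canvas point mapping is exact (round-trip
error below 1e-9 px; mapping back from the padded margin is an error, since
no original pixel exists there). CLAHE runs with `clip_limit = 2` and an
8×8 tile grid by default; the image is edge-padded to a tile-grid multiple
and cropped back, so any size is accepted, and a constant image is returned
unchanged (it has no contrast to amplify). DICOM ingestion covers
single-frame explicit-VR little-endian files and passes PixelSpacing
through; multi-frame files are rejected outright rather than silently
taking the first frame.

# The synthetic-pelvis generator

The generator is the package's test substrate: it builds bilateral
landmark geometry *from* the quantities the engine is supposed to recover,
so inverse consistency is exact by construction at zero noise.

Scene construction, per hip: Y sits `hip_halfwidth` from the midline on the
Hilgenreiner baseline; E is placed from the acetabular-index parameter
along a roof segment of length `roof_length`; the undisplaced C from the
CE-angle parameter at distance `c_to_e_dist` from E; H below C by
`metaphysis_offset`. A per-hip displacement `(lateral, superior)` then
moves C and H — this is the severity dial that drives the grades — and the
whole scene can rotate by `pelvic_rotation_deg` about the canvas center.
Shenton arcs are sampled from one circle spanning the pubis and neck
region, with the neck arc attached to the femur (it moves with the
displacement), so undisplaced hips are intact and displaced ones break the
arc by roughly the displacement magnitude.

Default scales — `hip_halfwidth = 100` px, `head_radius = 20` px,
`roof_length = 35` px, `c_to_e_dist = 1.8 * head_radius`,
`metaphysis_offset = (0, 25)` px, canvas 1333×800 — approximate pediatric
AP pelvis proportions at model-canvas resolution. Cohort sampling draws
per-hip acetabular indices from N(25°, 4°) and CE angles from N(19°, 6°),
truncated to plausible pediatric ranges; these centers and spreads sit in
the range that surgeons and automated systems report for this age group.
Landmark jitter is isotropic Gaussian per coordinate, independent across
landmarks, applied to the *detection bundle* only (ground truth stays
clean). Published detector evaluations report per-landmark mean distance
errors of about 4–5.4 px; since the mean radius of a 2D isotropic Gaussian
is σ·√(π/2), σ = 3.7 px reproduces that scale (≈ 4.64 px) and is the
default study condition for noisy cohorts.

Grade-targeted sampling is by rejection against the package's own grading
code — displacements are proposed uniformly and kept when the clean-truth
IHDI grade matches the target — rather than by inverting the region
geometry. This keeps the grading module the single source of truth for the
boundaries, at a modest cost (a handful of proposals per hip).

What the generator does **not** emulate: soft tissue, exposure variation,
occlusion, age-dependent ossification shape, correlated detector errors, or
out-of-plane (3D) pelvic tilt. Passing tests therefore demonstrate the
correctness of the measurement geometry and statistics under the stated
error model — not clinical performance of any detector on real
radiographs.

# Evaluation statistics

Reliability of continuous indices uses Cronbach's alpha over a
subjects × raters (or runs) matrix, with sample (n−1) variances — alpha's
value depends on that convention, so it is fixed and documented. Alpha at
or above 0.75 is reported as satisfactory. A variance-components ICC(2,1)
is provided as a clearly labeled alternative but is off by default in
reliability reports. Categorical agreement uses Cohen's kappa, ordinal
grades use linearly weighted kappa (`w_ij = 1 − |i−j|/(k−1)`), with the
conventional bands ≤ 0.40 poor-to-slight, 0.41–0.75 moderate, > 0.75
perfect. Landmark accuracy uses the per-landmark, per-side mean Euclidean
distance error; predictions missing a landmark the truth has are excluded
from the mean and reported as a separate miss count, since averaging a
placeholder distance would bias the error. MDE is reported in the pixel
space of the landmarks it is given — canvas pixels for canvas-space
cohorts; when the canvas transform is known, mapping through it rescales
distances by `1/scale`, so both spaces are recoverable.

Because the engine is deterministic, running it twice on identical inputs
gives identical measurement columns, and alpha across such duplicate runs
equals 1 *exactly* in floating point (duplicated columns make the variance
ratio a power-of-two quotient). The test-retest check in the acceptance
suite asserts exact equality, not a tolerance.

# Numerical choices and degenerate inputs

* Coincident Y points (Hilgenreiner undefined), E = Y (degenerate roof),
  C = E (degenerate coverage ray), non-positive radii and tolerances all
  raise immediate errors rather than producing angles from noise.
* The Hilgenreiner direction is canonicalized to `x ≥ 0`; rigid-motion
  invariance of the indices holds for rotations below 90°, beyond which
  the stored `lateral_sign` semantics (defined on image axes) no longer
  apply to the rotated image.
* Exact ties on grading lines are classified toward the lower grade with a
  1e-9 px flagging tolerance. Points within ~1e-13 of a boundary can be
  classified differently by algebraically equivalent re-implementations —
  the oracle-equivalence tests therefore sample off-boundary grids and
  exercise exact ties through dedicated constructed cases.
* The Kåsa circle fit solves a 3-parameter linear least-squares problem via
  QR; rank below 3 (collinear arc) is reported as indeterminate instead of
  extrapolating an enormous circle.

# Problem sizes in the test and acceptance suites

The suites run on cohorts sized to the questions they answer: 133 cases
(two hips each) for the test-retest reliability check, mirroring a
realistic external-validation cohort; 200 cases for noise-free parameter
and grade recovery; 500 cases for the Rayleigh MDE calibration (standard
error ≈ 0.11 px per landmark cell); 10⁴-point grids per hip side for
grading-oracle equivalence; 10³ random rays for monotonicity; 100 random
tables for the weighted-kappa oracle. The full suite completes in well
under two minutes on a single core.

# Known limitations

* Shenton's line is a geometric proxy with a fixed-tolerance circle rule,
  not a learned radiologist judgment; it needs explicit arc contours.
* The Tönnis rim band is one defensible operationalization of "at the level
  of the rim"; alternatives (pure head-center level comparison) would shift
  borderline 2/3/4 calls.
* AHI measures against the circle model of the head, not the ossified
  contour.
* The generator's error model is uncorrelated isotropic Gaussian jitter;
  real detectors err in structured ways (e.g. along bone edges), which
  affects variance but not the geometry being tested.
* No 3D or ultrasound (Graf) geometry, and no femoral neck-shaft angle.
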