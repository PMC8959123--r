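# hipmorph

Radiographic morphometry and dislocation grading for the pediatric hip.

Developmental dysplasia of the hip (DDH) spans a spectrum from a shallow
acetabulum to full dislocation in infants and toddlers. On an
anteroposterior (AP) pelvic radiograph the diagnosis rests on a small set of
geometric constructions over four per-hip landmarks:

- **E** — superolateral margin of the bony acetabulum,
- **Y** — center of the tri-radiate cartilage,
- **C** — center of the femoral head ossific nucleus (often invisible in
  young infants),
- **H** — midpoint of the superior margin of the ossified femoral
  metaphysis.

`hipmorph` is the measurement and classification engine that turns those
landmarks into the standard indices and grades. It is aimed at researchers
building or validating automated DDH measurement pipelines: the landmark
*detector* is pluggable (any learned or manual source that emits the
landmark JSON dialect works), while everything downstream of detection —
reference lines, indices, grades, reliability statistics — is implemented
and tested here, with a parametric synthetic-pelvis generator supplying
ground truth.

## What it computes

With Hilgenreiner's line *h* (through both Y points) as the horizontal
reference and Perkin's line *p* (perpendicular to *h* through E):

- **Acetabular index (AI)** — the angle between the acetabular roof segment
  Y→E and *h*; larger = shallower socket.
- **Center-edge angle of Wiberg (CE)** — the angle at C between the
  superior perpendicular to *h* and the ray C→E; smaller or negative =
  less femoral-head coverage.
- **Acetabular head index (AHI)** — 100 · A/B, where B = femoral head width
  along *h* and A = the covered part, from the medial head edge to the
  projection of E.
- **Shenton's line** — continuity of the pubic-ramus / femoral-neck arc,
  checked by fitting a circle to the pubic arc and thresholding the maximum
  radial residual of the neck arc (default 5 px).
- **Tönnis grade (1–4)** — position of C relative to Perkin's line and the
  acetabular-rim band.
- **IHDI grade (I–IV)** — quadrant of H relative to *h*, *p*, and the 45°
  inferolateral diagonal from the *h*–*p* junction; usable when the ossific
  nucleus (C) is absent.

Supporting modules provide image preprocessing (aspect-preserving resize
onto a 1333×800 canvas with zero padding, CLAHE contrast enhancement,
PNG/DICOM ingestion with pixel-spacing pass-through), the
segmentation-gated suppression of spurious C detections (a C landmark is
only trusted when a femoral-head ROI exists for that side), and evaluation
statistics: per-landmark mean Euclidean distance error (MDE), Cronbach's
alpha, Cohen's and linearly weighted kappa, and confusion-matrix metrics.

## Worked example

A small synthetic case ships with the package: a normal left hip and a
subluxated right hip (femoral head displaced 25 px laterally, 12 px
superiorly), with 2 px Gaussian landmark jitter emulating detector error.

```r
library(hipmorph)

path <- system.file("extdata", "synthetic_demo_landmarks.json",
                    package = "hipmorph")
report <- measure_bundle(read_landmark_json(path))
print(report[, 1:8], digits = 4)
#>    side acetabular_index_deg ce_angle_deg ahi_percent   shenton tonnis ihdi
#> 1  left                25.12        24.21       88.52    intact      1    1
#> 2 right                39.45       -50.06      -17.97 disrupted      2    2
#>   ihdi_roman
#> 1          I
#> 2         II
```

The left hip reads as normal: acetabular index ≈ 25°, CE angle ≈ 24°, 89 %
head coverage, intact Shenton line, Tönnis 1 / IHDI I. The displaced right
hip shows the dysplastic pattern: a steep roof (39°), a strongly negative
CE angle and negative coverage (the head center is lateral to E), a
disrupted Shenton line, and Tönnis 2 / IHDI II.

Cohorts with known ground truth come from the generator:

```r
cohort <- sample_cohort(50, grade_mix = c(0.4, 0.3, 0.2, 0.1),
                        noise_sigma_px = 3.7, seed = 1)
report <- measure_cohort(cohort)
table(report$ihdi_roman)
```

A thin command-line front end (`inst/exec/hipmorph.R`) exposes the same
functionality as `measure`, `synth`, `eval`, and `reliability` verbs.

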