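Package: hipmorph
Title: Radiographic Morphometry and Dysplasia Grading for the Pediatric Hip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and classification engine for developmental dysplasia
    of the hip (DDH) on anteroposterior pelvic radiographs. From per-hip
    anatomical landmarks (lateral acetabular margin E, tri-radiate cartilage
    center Y, femoral head center C, metaphysis midpoint H) it constructs
    Hilgenreiner and Perkin reference lines, computes the acetabular index,
    center-edge angle of Wiberg and acetabular head index, checks continuity of
    Shenton's line, and assigns Toennis and IHDI dislocation grades. Includes
    image preprocessing (aspect-preserving resize with zero padding, CLAHE
    contrast enhancement, DICOM/PNG ingestion), a pluggable landmark-provider
    interface with segmentation-gated suppression of spurious femoral-head
    centers, a parametric synthetic-pelvis generator with known ground truth,
    and evaluation statistics (landmark mean distance error, Cronbach's alpha,
    Cohen's and linearly weighted kappa, confusion-matrix metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
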