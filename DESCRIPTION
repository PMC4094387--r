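Package: ihcquant
Title: Per-Cell Quantification of Chromogenic Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated per-cell quantification of brightfield
    immunohistochemistry (IHC). Converts RGB images of hematoxylin/AEC
    stained tissue to optical density, unmixes the stains by color
    deconvolution, segments nuclei from the hematoxylin master marker with
    a marker-controlled watershed, builds ring-shaped perinuclear masks for
    cytoplasmic measurement, and assembles a per-cell feature table with
    scattergram gating. Downstream statistics cover knockout-anchored
    background cut-offs, gene-dosage (2:1:0) ratio recovery, positive-cell
    fractions, nuclear/cytoplasmic translocation ratios, four-level ordinal
    scoring and inter-rater agreement (percent agreement and linearly
    weighted kappa). A seeded virtual-slide simulator with full per-cell
    ground truth supports validation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
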