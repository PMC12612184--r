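Package: curvchip
Title: Quantitative Analysis for Hydraulically Controlled Curvature Organ Chips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for curvature organ-chip experiments on corneal
    stromal cells. Converts measured dome chord angles to spherical-cap
    geometry and keratometric diopters, solves the axisymmetric inflation of a
    clamped elastic membrane to obtain meridional and hoop stress profiles
    with center/slope/edge region summaries, quantifies region-resolved
    corrected total cell fluorescence (CTCF) from tiled microscopy images,
    measures cell alignment with structure-tensor orientation histograms
    (crossing angle and alignment efficiency), computes colony coverage rates
    and fold changes over time, and performs relative qPCR quantification
    (2^-ddCt) with one-way ANOVA and Scheffe post-hoc tests. A synthetic-data
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    deSolve,
    stats,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
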