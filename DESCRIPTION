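Package: microvasq
Title: Morphometric Quantification of Tumor Microvasculature from
    Contrast-Free Ultrasound Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for quantitative
    high-definition microvasculature imaging (HDMI) of focal lesions:
    singular-value-decomposition clutter filtering of slow-time ultrasound
    ensembles, power-Doppler formation, background equalization and
    Hessian-based vessel enhancement, lesion-mask handling with perilesional
    dilation, binarization, thinning and skeleton-graph construction, nine
    vessel-morphometry biomarkers (vessel density, segment and branch-point
    counts, distance-metric tortuosity, diameter, box-counting fractal
    dimension, Murray's-law deviation, bifurcation angle), and two-group
    Wilcoxon rank-sum screening.  A synthetic vascular-tree generator
    provides exact ground truth for every stage, including two-group
    cohorts emulating benign versus malignant lesion morphology.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
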