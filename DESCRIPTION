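Package: nemaquant
Title: Posture, Tracking and Calcium Trace Quantification for C. elegans Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-segmentation analysis of Caenorhabditis elegans imaging data.
    Starting from per-frame binary masks produced by any segmenter, the package
    filters and deduplicates candidate masks, extracts ordered medial-axis
    centerlines with self-touch correction, and quantifies morphometry
    (area, perimeter, length, width profiles), swimming posture (Gaussian-weighted
    body curvature, bending amplitude, shape classes, wavelength, wave number,
    spatial and temporal undulation frequency), crawling behavior (head-tail
    assignment, head-bend angles, movement-state classification, behavioral bouts,
    path metrics), and calcium-imaging fluorescence of neuronal compartments with
    distance-transform background correction and signed head angles. A synthetic
    worm generator with exact analytic ground truth supports validation of every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    signal,
    pracma,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
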