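Package: growthlines
Title: Digital Fate Mapping and Growth-Line Analysis on 4D Stage-Mesh Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing anisotropic tissue growth in the embryonic
    forebrain with corresponding surface-mesh series ("4D models").  The
    package transports in-silico dye patches through shape-key mesh
    interpolation, quantifies the resulting growth lines (expansion,
    elongation, orientation, convergence, spot/line/V shape calls), scores
    patches against named outcome regions and builds per-zone frequency
    matrices, and provides landmark morphometry (line-ratio and angle
    measurements, thresholded expression-area quantification, Student and
    Welch t tests) plus a single-cell gene-set stage (marker-based cell
    filtering and binned-control module scores).  A synthetic-embryo
    generator produces corresponding meshes under known deformation fields
    with ground truth, so the whole pipeline is testable without imaging or
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    mgcv,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
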