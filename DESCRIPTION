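Package: histoflow
Title: Single-Cell Cytometry on Immunofluorescent Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-cell image-analysis pipeline for quantifying myeloid-cell
    populations in multiplex immunofluorescently stained brain tissue.
    Segments cells from pairs or triples of marker channels via adaptive
    thresholding and a combined master mask, measures per-cell mean
    intensities, assigns cells to populations with flow-cytometry-style
    polygon gates in 2D intensity space, registers sequential staining
    rounds by nuclei-landmark affine estimation, measures amyloid-beta and
    tau pathology load, classifies cells as plaque / plaque-adjacent /
    non-plaque by incremental circular dilation, and applies the
    accompanying statistical decision procedures. Includes a ground-truthed
    synthetic image generator so every stage is testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
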