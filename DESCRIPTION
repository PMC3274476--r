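Package: spimpipe
Title: Light-Sheet Microscopy Image Pipeline for Live Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for single-plane illumination microscopy (SPIM)
    stacks of multicellular tumor spheroids with fluorescently labelled nuclei.
    Removes stationary stripe artifacts by MAP estimation under a
    white-noise-convolved-with-elementary-pattern model (total-variation
    regularized, primal-dual solver), registers and fuses opposing 0/180 degree
    views, compensates time-lapse drift, detects nuclei in 3D and classifies
    mitotic versus interphase figures, situates detections relative to the
    fitted spheroid surface, tracks divisions over time and scores mitotic
    duration and drug-induced mitotic arrest. A seeded synthetic SPIM-spheroid
    generator with exact ground truth makes every stage testable without real
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
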