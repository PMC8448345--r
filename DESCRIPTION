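Package: spinsym
Title: Symmetry Breaking and Rotation of the Anaphase II Spindle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the spontaneous symmetry breaking that drives
    anaphase II spindle rotation in mouse oocytes. Provides an overdamped
    mechanical model of two cortex-attracted DNA clusters under cytokinetic
    furrow ingression, a closed-form model of symmetry-breaking-time
    distributions, generators of synthetic 4D fluorescence stacks, cortical
    images and speckle movies with known ground truth, a 3D segmentation
    and proximity-tracking pipeline for DNA clusters, rotation-onset and
    polarity metrics, Euclidean-distance-map cortical intensity profiling,
    and two-pass cross-correlation particle image velocimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
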