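Package: xrh
Title: Immunofluorescence-Guided Segmentation of 3D Features in Micro-CT of FFPE Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correlating 2D wide-field fluorescence section images
    with 3D micro-computed tomography (microCT) volumes of formalin-fixed
    paraffin-embedded (FFPE) soft tissue. Provides automated
    section-to-volume registration (multi-scale feature correspondence and
    thin-plate-spline warping), quantitative registration accuracy scoring
    based on tissue/airspace overlap, seeded active-contour segmentation of
    blood vessels from the microCT volume, microCT-constrained morphological
    interpolation of sparse 2D immunofluorescence labels into 3D, and a
    synthetic lung-phantom generator with ground-truth labels and simulated
    sectioning deformations so the entire pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    png,
    RNifti,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
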