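Package: BipolarCoding
Title: Functional Analysis of Retinal ON Bipolar Cell Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing two-photon calcium imaging of retinal ON
    bipolar cell axons: rigid registration, morphological ROI segmentation
    and consolidation, temporal-frequency (F1) analysis with GCaMP6f
    kinetics correction, center-surround spot-response statistics,
    reference-based functional cell-type classification with IPL-depth
    priors, nonmetric multidimensional scaling of population response
    distances with batch-effect testing, feature-sensitivity analysis of
    naturalistic movies including Horn-Schunck optical flow, and
    length-constant estimation along axon arbor skeletons. A synthetic-data
    module generates stimuli, model-cell responses, rendered image series
    and arbor skeletons with the statistical structure the analyses assume,
    so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    MASS,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
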