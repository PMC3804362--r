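Package: morphostage
Title: Statistical Shape Models of Liver and Spleen for Cirrhosis Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphological analysis of the liver and the spleen for
    computer-aided diagnosis and staging of chronic liver disease.
    Builds statistical shape models (point distribution models) of the
    liver, the spleen, and the joint liver-spleen system from
    corresponded surface meshes; extracts surfaces from segmented label
    volumes, standardizes them to a fixed vertex count, aligns them
    rigidly, and establishes dense correspondence by robust point
    matching with thin-plate-spline warping under deterministic
    annealing (TPS-RPM). Diagnostically effective deformation modes are
    selected by combining accumulated variance contribution with an
    uncentered correlation against clinical labels; subjects are
    classified normal/abnormal by nearest neighbour and their disease
    stage is estimated by epsilon-support-vector regression on the
    selected mode coefficients. Includes a synthetic cohort generator
    with stage-linked deformation for validation, and a leave-one-out
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    e1071,
    igraph,
    RNifti,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
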