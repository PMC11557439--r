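Package: hemocascade
Title: Cascaded Segmentation, Subtype Classification and Outcome
    Modelling for Traumatic Brain Injury CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A coarse-to-fine analysis cascade for intracranial
    hemorrhage on axial head CT: a slice-level binary hemorrhage filter,
    a two-stage encoder-decoder segmenter with region-of-interest (ROI)
    cropping and vote fusion, a mask-guided global/local multi-label
    hemorrhage-subtype classifier, hematoma volumetry, and 14-day
    mortality models that augment CRASH clinical predictors with
    automatically extracted hematoma volume and subtype features.
    Includes a synthetic phantom and cohort generator so the whole
    pipeline is exercisable and testable without any external imaging
    data, and small CPU-trainable network backbones implemented with
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    png,
    EBImage,
    jsonlite,
    randomForest,
    pROC
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
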