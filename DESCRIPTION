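Package: muscleseg
Title: Automated Thigh Muscle Segmentation and Fat-Fraction Quantification
    for Fat-Water Decomposition MRI
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for quantifying intramuscular fat
    infiltration in the thigh from fat-water decomposition (Dixon) MRI.
    Bilateral water/fat volumes are split into single-thigh volumes,
    subcutaneous fat and skin are removed automatically (K-means intensity
    clustering, order-statistic filtering, hole filling and dilation), and a
    two-channel slice-wise U-net segments four functional muscle groups
    (quadriceps femoris, sartorius, gracilis, hamstrings). Predictions are
    consolidated by largest-3D-component postprocessing, fat-fraction maps
    are computed as fat/(water+fat), and per-ROI mean fat fraction and
    volume are reported together with Dice overlap, percent volume
    difference, intraclass-correlation reproducibility and one-tailed Welch
    group comparisons. A synthetic bilateral-thigh phantom generator with
    known ground truth supports desk-scale training, testing and method
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Segmentation, Preprocessing, Visualization
RoxygenNote: 7.3.3
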