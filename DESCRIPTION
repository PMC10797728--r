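Package: tmegraph
Title: Spatial Tumor-Microenvironment Graph Features for Chemotherapy
    Response Prediction from H&E Tiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step analysis of hematoxylin-and-eosin histology for
    predicting neoadjuvant chemotherapy response in breast cancer.
    Step one classifies 224x224 tissue tiles into histology classes from
    an 80-dimensional engineered texture feature vector (gray-level
    co-occurrence, Gabor, local binary pattern, Tamura, and histogram
    families) computed on the stain-deconvolved hematoxylin channel, and
    assembles per-patient spatial histology classification maps. Step two
    builds tumor-microenvironment graphs over connected tile clusters for
    every histology class pair, extracts 20 spatial features per pair
    (texture averages, spectral node statistics, minimum-spanning-tree
    connectivity), selects the most discriminative features by ReliefF,
    and predicts pathological complete response versus residual disease
    under leave-one-out cross-validation. A synthetic-data generator with
    a planted outcome-linked spatial interaction makes every stage
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    grDevices,
    igraph,
    jsonlite,
    png,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
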