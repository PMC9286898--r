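Package: cdrscreen
Title: Compound-Disease Relationship Prediction from Descriptor-Fusion
    Grayscale Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts compound-disease relationships (CDRs) by fusing a
    compound's molecular-descriptor vector with a disease's
    symptom-descriptor vector into an additive two-dimensional matrix,
    rendering it as an 8-bit grayscale image, and classifying the image
    with a convolutional neural network trained by stochastic gradient
    descent. Includes benchmark assembly with negative sampling and
    class-ratio series, random and disease-/compound-held-out splits,
    confusion-matrix and ROC/AUC evaluation with relative-change
    calculators, library screening with annotation filters and a
    high-confidence probability cut, SVM-RFE feature ranking of
    structural and ADME descriptors, and a planted-rule synthetic data
    generator so the full pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
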