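Package: cmrtexture
Title: Texture-Based Outcome Prediction for Cardiac MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable radiomics pipeline for short-axis cardiac magnetic
    resonance images: region-of-interest texture feature extraction
    (histogram, grey-level co-occurrence matrix, run-length matrix,
    absolute gradient, causal autoregressive model, and Haar wavelet
    energies), reliability-based feature selection using intraclass
    correlation coefficients and correlation-matrix redundancy pruning,
    and cross-validated machine-learning classification of a binary
    clinical outcome with Hanley-McNeil AUC comparison. Includes a
    fully synthetic cohort generator emulating a takotsubo-syndrome
    imaging study (paired T2-weighted and late-gadolinium-enhancement
    images, repeated reader segmentations, demographics, and event
    labels) so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    nnet,
    rpart,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
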