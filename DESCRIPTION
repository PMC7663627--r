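Package: tfrnose
Title: Gas-Flow-Independent Odor Identification from Transfer Function Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature extraction and classification for multichannel chemical
    sensor arrays based on transfer function ratios (TFRs): pairwise spectral
    ratios of channel outputs that cancel the shared gas-concentration input
    and are therefore independent of gas delivery. Provides windowed FFT
    feature extraction from labeled recordings, Davies-Bouldin cluster-quality
    evaluation with PCA score projection, leakage-free nested cross-validated
    classification (multinomial logistic regression and random forests),
    spectral analysis of binary free-hand measurement protocol waveforms, and
    a linear time-invariant sensor simulator with a closed-form TFR oracle for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    glmnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
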