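Package: rscmotion
Title: Motion Recognition from Rate-of-Stress-Change Force Myography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hand- and wrist-motion recognition from
    multichannel rate-of-stress-change (RSC) force-myography signals recorded
    with piezoelectret pressure sensors. Provides a seeded synthetic-session
    generator emulating the transient (derivative-like) piezoelectret
    response, power-line notch filtering, sliding-window segmentation,
    thirteen time-domain features, four classifiers (LDA, KNN, two-hidden-
    layer ANN, one-vs-one RBF SVM), repetition-blocked k-fold cross-validated
    accuracy with confusion matrices, sequential forward feature selection,
    and window-length and white-noise robustness sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
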