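Package: periopnet
Title: Serial Neural Prediction of Surgery and Anesthesia Emergence Duration
Version: 0.1.0
Authors@R:
    person("Perioperative", "Informatics Lab", email = "periopnet@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting operating-room time requirements from
    preoperative tabular records. Implements an automatic class-balancing and
    noise-augmentation preprocessing algorithm for imbalanced 4-class duration
    labels, a seeded multilayer-perceptron classifier trained with Adam and
    cross-entropy, a replicate grid-search architecture-selection protocol with
    one-tailed t-test comparisons and runtime accounting, and a two-stage
    serial system in which the predicted surgery-duration class feeds the
    anesthesia-emergence predictor. A synthetic perioperative cohort generator
    provides reproducible test beds in place of private hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
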