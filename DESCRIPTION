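Package: armuse
Title: Functional Upper-Extremity Use from Bilateral Wrist Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for real-world functional upper-extremity
    use in stroke from bilateral wrist-worn accelerometers. Ingests raw
    tri-axial acceleration streams and frame-level video annotations,
    synchronizes the two clocks via z-axis shake-pulse trains, transfers
    majority-vote consensus labels onto the sensor timeline, partitions each
    limb's stream into 2-second blocks, extracts a 17-feature summary per
    block, trains subject- and limb-specific random-forest classifiers with
    stratified k-fold cross-validation, and computes per-limb functional-use
    proportions and the paretic/less-affected use ratio. Includes a
    count-threshold baseline, a concurrent-validity statistics suite (Pearson
    correlations with Fisher-z intervals, linear fits, Bland-Altman agreement,
    varimax-rotated principal-component factor analysis), and a seeded
    synthetic-data generator producing two-limb recordings, noisy annotator
    tracks, and coupled clinical scores for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
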