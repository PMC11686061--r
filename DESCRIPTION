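Package: dbsconnect
Title: Phase-Lag-Index Connectivity Analysis of STN-DBS Response in
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for source-space EEG functional connectivity
    in Parkinson's disease patients treated with subthalamic deep brain
    stimulation (DBS). Builds phase-lag-index (PLI) networks from ROI time
    series recorded during a three-stimulus visual oddball task, summarizes
    a 14-region bilateral motor subnetwork by its first eigenvariate and
    tests DBS ON vs OFF differences with covariate-adjusted signed-rank
    tests under FDR control, relates the DBS OFF motor pattern to motor
    improvement (MDS-UPDRS III), extracts whole-brain PCA connectivity
    patterns of the ON state and correlates them with neuropsychological
    T-scores, and classifies optimal DBS responders with a nested
    leave-one-out linear-SVM procedure built on a 4-standard-deviation
    connectivity-profile rule. Ships a synthetic coupled-oscillator and
    planted-effect cohort generator so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
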