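Package: gazeaoi
Title: Area-of-Interest Gaze Metrics for Attention-Shift Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screen-based eye-tracking studies that score gaze
    streams against declared areas of interest (AOIs). Reads delimited
    gaze-sample exports and clinical rosters, applies screen-looking and
    valid-trial inclusion filters, assigns each sample an AOI / vacant /
    off-screen / invalid label, and computes classical metrics (total gaze
    count, total fixation time, mean pupil size) together with
    attention-shift metrics: AOI switch counts, favored versus unfavored
    AOI shifts along a declared per-block pathway, and AOI vacancy counts
    with their per-time-unit rate. Includes rank-sum group comparisons,
    metric-versus-severity regression, severity-mapped and ROC-scanned
    diagnostic cutoffs with sensitivity and specificity, and a Markov-chain
    gaze simulator for synthetic cohorts and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
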