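Package: facescreen
Title: Dementia Screening Pipelines over Facial Feature Time Series
Version: 0.1.0
Authors@R:
    person("facescreen", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tested, reusable pipelines for screening dementia from
    pre-extracted facial-feature streams: face-mesh landmark normalization
    with PCA reduction and an LSTM sequence classifier; facial action unit
    (AU) intensity segment statistics classified with an RBF-kernel SVM and
    aggregated to subject-level decisions by threshold voting under
    leave-one-subject-out evaluation, with max-accuracy and equal-error-rate
    operating points. Includes a synthetic cohort generator emulating the
    structure of clinical interview video features (subjects with repeated
    sessions, 30 FPS streams, group-level shifts in action-unit means and
    variances) so the full analysis is testable without access to restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
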