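Package: brbrehab
Title: Belief-Rule-Base Assessment of Upper-Limb Rehabilitation Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, runs and trains belief rule base (BRB) models for grading
    the recovery status of a patient's upper limb from three robot-measured
    attributes: active resistance torque (ARTUL), rehabilitation training time
    (RTT) and mean amplitude of muscle strength (MAMS). Inference uses the
    analytic evidential reasoning (ER) aggregation rule; model parameters
    (rule weights, attribute weights, consequent belief degrees) are learned
    from labelled records by constrained minimisation of mean squared error.
    Includes a synthetic patient-record generator, an evaluation and
    baseline-comparison harness, JSON rule-base and CSV dataset input/output,
    bundled expert-elicited and trained reference rule bases, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    optparse
Suggests:
    testthat (>= 3.0.0),
    nnet,
    e1071
LinkingTo:
    Rcpp
Config/testthat/edition: 3
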