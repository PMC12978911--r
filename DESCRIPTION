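Package: crtadhere
Title: Cluster-Level Summary Analysis of Stratified Cluster-Randomized
    Adherence Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the design, simulation and primary-outcome analysis
    of stratified cluster-randomized trials of physician guideline
    adherence with a binary prescription-level outcome. Implements
    eligibility filtering and adherence adjudication of antibiotic
    prescription records, cluster-level summary inference (stratified
    ratios of geometric mean risks and risk differences with
    inverse-variance stratum weights and a stratified t-test),
    covariate adjustment through cluster-specific ratio residuals from an
    individual-level logistic model that excludes the treatment arm,
    sample-size calculation from a between-cluster coefficient of
    variation, stratified randomization with allocation concealment, and a
    synthetic-trial generator with a stored truth record for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
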