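Package: crossgen
Title: Cross-Study Generalizability of Passive Mobile-Sensing Symptom
    Prediction
Version: 0.1.0
Authors@R:
    person("crossgen", "authors", email = "maintainer@crossgen.invalid",
           role = c("aut", "cre"))
Description: Harmonizes heterogeneous longitudinal mobile-sensing studies
    into a shared day-level feature and ecological momentary assessment
    (EMA) outcome schema, runs leave-one-subject-out cross-validation
    experiments comparing combined versus single-study training of
    gradient-boosted regression trees (Huber loss), with optional SMOTE
    oversampling and nearest-neighbour personalization, and quantifies
    when pooling studies helps via the Proxy-A distance and clustered
    nonparametric sensitivity analyses.  Includes a synthetic two-study
    generator emulating the statistical structure of public mobile-sensing
    datasets so the full pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    FNN,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
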