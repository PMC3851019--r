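Package: hcstopics
Title: Topic Modeling of High Content Screening Dose-Response Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts multi-endpoint high content screening (HCS)
    dose-response measurements into a discretized document-term corpus,
    fits a latent Dirichlet allocation (LDA) topic model by collapsed
    Gibbs sampling, and scores "diagnostic topics" that link groups of
    in vitro cellular endpoints to in vivo histopathology classes
    (early necrosis, late necrosis, no necrosis). Includes a synthetic
    data generator with planted endpoint-group structure so the whole
    pipeline is testable without proprietary assay data: control
    normalization, log-dose trapezoidal AUC, per-column binning,
    corpus construction, sampler diagnostics, topic matching across
    runs, per-class diagnostic scores and a transitive in vitro to
    in vivo linkage report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
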