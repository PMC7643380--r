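Package: longnet
Title: Longitudinal Multilayer Brain Network Reconfiguration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds positive weighted functional connectivity layers from
    region-of-interest time series, assembles them into per-subject ordinal
    multilayer networks, maximizes the multilayer modularity quality
    function with a generalized Louvain algorithm (including the
    'moverandw' randomization), and derives the temporal reconfiguration
    metrics flexibility, promiscuity, cohesion strength, disjointedness,
    module allegiance and network recruitment. Includes temporal and nodal
    null models with Welch-test comparisons, group-level association
    models (age regressions with partial eta squared, metric
    intercorrelations, per-subject cognitive change slopes and
    change-change correlations), and a synthetic longitudinal cohort
    generator so the whole pipeline is testable without imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
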