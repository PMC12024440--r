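Package: edgefc
Title: Edge-Centric Functional Connectivity and Edge-Community Overlap Analysis
Version: 0.1.0
Authors@R: person("A.", "Maintainer", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Tools for edge-centric analysis of parcellated functional
    time series. Builds per-frame co-fluctuation edge time series from
    z-scored component signals, computes the edge functional connectivity
    (eFC) matrix, clusters edges into overlapping communities with
    restarted k-means over a sweep of k, and quantifies community overlap
    through node participation profiles, normalized community entropy
    (component- and network-level) and node-pair community similarity.
    Includes covariate-adjusted two-group statistics with Bonferroni
    control, a latent-factor synthetic cohort generator with known edge
    community structure for end-to-end validation, and a reproducible
    pipeline driver with JSON configs and run manifests.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
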