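Package: cortisim
Title: Simulated Development of Cortical Sheet Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of a developing two-dimensional cortical
    sheet in which rectangular areas of graded neuron density appear along
    configurable spatiotemporal growth layouts while axons grow as random
    walks and form synapses stochastically on spatial proximity. Provides
    extraction of directed area-level connectomes, binned connection
    frequency and rank-correlation statistics, logistic-regression edge
    prediction with McFadden's pseudo-R2, and a simulation-trained
    linear-kernel classifier with dual posterior-probability thresholds,
    permutation-based chance distributions, sign tests and analysis of
    variance for cross-instance validation, together with generators for
    synthetic tract-tracing-style connectivity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
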