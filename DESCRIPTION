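Package: lamflow
Title: Laminar Cortical Signal-Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laminar (linear multi-contact probe)
    extracellular recordings from visual cortex: LFP and multi-unit envelope
    (MUAe) conditioning, inverse current-source-density (iCSD) depth profiles
    with Vaknin boundary handling and layer-4c sink alignment, transient
    response-latency model fitting, induced spectral power, phase-triggered
    averaging across frequency bands, band-integrated Geweke spectral Granger
    causality with a time-reversal control, and cluster-mass permutation
    statistics. Includes a synthetic laminar-session generator with full
    ground truth (planted current sinks, per-layer latencies, directed
    cross-layer oscillatory coupling, common-noise mixing) so that every
    analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
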