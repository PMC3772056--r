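Package: valueframes
Title: Frames of Reference in Value-Guided Choice: Behavioural Modelling
    and Time-Frequency Cluster Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how the brain
    frames value-guided decisions in 'goods' versus 'action' coordinates.
    Provides a synthetic-data generator for two-option risky-choice sessions
    (prospect-theory softmax agents) and source-level oscillatory epochs with
    injected value- and choice-locked beta-band power modulations; maximum-
    likelihood fitting and BIC comparison of prospect-theory and objective
    expected-value choice models; logistic-regression analysis of choice
    determinants; blink detection and template-topography artifact removal;
    Morlet wavelet single-trial time-frequency power regression; group-level
    sign-flip cluster-based permutation inference across the time-frequency
    plane; and peak-latency and region-by-trial-type interaction contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
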