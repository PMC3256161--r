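Package: fretcssr
Title: Causal-State Model Inference for Noisy Single-Molecule Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers hidden Markov models from noisy time series that cluster
    around discrete levels, such as single-molecule FRET trajectories.
    Observations are discretised with a Gaussian mixture model (selected by
    AIC) into certain symbols plus an explicit null symbol for ambiguous
    points, a null-aware adaptation of the Causal State Splitting
    Reconstruction (CSSR) algorithm infers a minimal unifilar machine from
    the certain subsequences, and the result is converted into physical
    kinetics (transition rates, dwell-time distributions).  Includes a
    simulator for symbol-emitting machines with Gaussian observation noise,
    forward and Viterbi algorithms for continuous observations, the Rabiner
    model distance for validating inferred against generating models, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
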