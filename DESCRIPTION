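Package: radarvitals
Title: Non-Contact Vital-Sign Monitoring with UWB Radar: Simulation, Heart-Rate
    Correction and RR-Interval Anomaly Detection
Version: 0.1.0
Authors@R:
    person("radarvitals", "maintainers", email = "radarvitals@example.org",
           role = c("aut", "cre"))
Description: Tools for studying ultra-wideband (UWB) radar vital-sign
    monitoring pipelines on calibrated synthetic data. Simulates the
    slow-time phase series induced by chest displacement from respiration
    and heartbeat, extracts respiration rate, heart rate, motion energy,
    motion status and target distance from phase series, generates tabular
    heart-rate correction datasets whose factor-versus-error Kendall tau-b
    structure is calibrated against published coefficients, trains a
    fully-connected correction network (PReLU, dropout, Adagrad) and a 1-D
    convolutional RR-interval anomaly detector (batch normalisation, Adam),
    and evaluates detection latency with a sliding-window latency statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
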