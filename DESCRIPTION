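Package: mitorate
Title: Birth-Death Kinetics Reconciliation for Cultured Cell Populations
Version: 0.1.0
Authors@R:
    person("Sam", "Okafor", email = "sokafor@example.org", role = c("aut", "cre"))
Description: Deterministic birth-death modelling of cultured cell
    populations that reconciles observed growth curves with division
    (mitotic-index) and death (TUNEL apoptotic-index) measurements.
    Converts occupancy indices into per-hour division and death rates,
    predicts exponential growth, and quantifies the excess ("hidden")
    death rate needed to reconcile prediction with observation, with
    bootstrap confidence intervals. Includes assay quantification rules
    (soft-agar colony size filtering, invasion field summaries,
    nuclei-density conversion), log-linear growth-curve fits and
    proportion/endpoint tests, an exact Gillespie birth-death simulator
    with an observation layer emulating hemocytometer counting and
    index scoring, and a deterministic simulate-analyze-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
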