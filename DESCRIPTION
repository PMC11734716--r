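Package: thermowire
Title: Metabolic Scaling of Developmental Time and Brain Wiring with Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a metabolic theory linking developmental temperature to
    developmental time and synaptic connectivity in insects: a quarter-power
    ontogenetic growth model with Boltzmann-Arrhenius temperature dependence,
    closed-form exponential fold-change laws for developmental time and for
    the number of synaptic partners, and predictions for development under
    periodic temperature cycles. Also provides the companion data-reduction
    procedures (connectome synapse-table filtering and partner allocation,
    odor-occupancy and walking-speed statistics for behavioral assays),
    estimation of the scaling factors from fold-change data with bootstrap
    uncertainty, and seeded synthetic-data generators for every input so the
    full pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
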