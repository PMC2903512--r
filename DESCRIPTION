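Package: cidpce
Title: Cost-Utility Markov Model of IVIG Versus Corticosteroids for CIDP
Version: 0.1.0
Authors@R: person("PATH", "Modelling", email = "modelling@example.org",
    role = c("aut", "cre"))
Description: A cohort Markov model comparing intravenous immunoglobulin
    (IVIG) with corticosteroid treatment for chronic inflammatory
    demyelinating polyneuropathy (CIDP) from a Canadian public-payer
    perspective. Provides a DerSimonian-Laird random-effects meta-analysis
    of IVIG response proportions, a 12-week-cycle state-transition engine
    with corticosteroid adverse-event tunnel states, QALY and cost accrual
    with discounting, deterministic one-way and scenario sensitivity
    analysis, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
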