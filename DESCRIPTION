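Package: fmtdc
Title: Dose Finding for Drug-Combination Cell-Therapy Trials with
    Feasibility and Late-Onset Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, conduct, and simulation tools for phase I
    dose-finding trials of drug combinations in which one agent is a
    manufactured cell-therapy product. Toxicity is modelled with a
    single-parameter probit continual reassessment method extended to
    partially ordered dose combinations via Bayesian model averaging over
    candidate simple toxicity orders, with time-to-event weighting of
    pending dose-limiting-toxicity outcomes so enrollment can continue
    during a long observation window. Manufacturing dose-feasibility is
    modelled with a Dirichlet-multinomial posterior over each patient's
    highest feasible cell dose, yielding a globally feasible dose set and
    an early-stopping rule. The package identifies the feasible maximum
    tolerated dose combination (FMTDC), provides decision support for an
    ongoing trial, and simulates operating characteristics over
    user-specified toxicity and feasibility scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
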