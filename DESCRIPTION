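Package: copdsim
Title: Individual-Level Microsimulation of COPD Natural History and
    Screening Cost-Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-level (microsimulation) model of the natural
    history and clinical management of chronic obstructive pulmonary
    disease (COPD) in the Chinese adult population, with a 3-month cycle
    and a lifetime horizon.  Simulates lung-function (FEV1) decline, GOLD
    staging, exacerbations, background and excess mortality, symptom-based
    and screening-based diagnosis (one-step questionnaire or two-step
    questionnaire plus portable spirometer), and treatment.  Provides a
    full cost-effectiveness layer: discounted QALYs and costs, ICERs, the
    dominance frontier with extended dominance, averted-event summaries,
    linkage-to-care scenario grids, one-way sensitivity sweeps,
    probabilistic sensitivity analysis and cost-effectiveness
    acceptability curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tibble,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
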