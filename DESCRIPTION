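Package: lcscreen
Title: Cost-Effectiveness Modelling of AI-Assisted Low-Dose CT Lung Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model of artificial-intelligence support at the
    baseline low-dose CT scan of lung cancer screening. A diagnostic decision
    tree (pre-test probability, sensitivity, specificity) feeds an annual-cycle
    Markov cohort model with tunnel states for staged detection of missed
    cancers and for the first year after resection. The package computes
    discounted lifetime costs and quality-adjusted life years per strategy,
    incremental cost-effectiveness ratios with dominance classification,
    deterministic (tornado) and probabilistic (Monte Carlo) sensitivity
    analyses, and threshold analysis on the admissible per-screen cost of the
    AI system. A per-patient microsimulation oracle and synthetic life-table
    generators make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
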