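Package: betaspe
Title: Beta-Belief Modelling of Global Self-Performance Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative modelling of how people form global self-performance
    estimates (SPEs) from trial-level local confidence and intermittent,
    valence-asymmetric performance feedback. Implements a Beta-distribution
    belief-updating model with asymmetric learning rates for feedback and
    confidence, symptom-linked distortion variants (D0-D6) in which a mental
    health score modulates the asymmetries or adds a report bias, group-level
    Bayesian estimation by adaptive MCMC with DIC model comparison and
    highest-density intervals, a study-design simulator (1-up-2-down
    staircase, rigged feedback scheduler, eight counterbalanced block orders),
    parameter- and model-recovery harnesses, and model-free diagnostics
    (baseline correction, within-participant z-scoring, confidence-quantile
    summaries and fixed-effects interaction tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
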