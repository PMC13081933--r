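Package: tiersim
Title: Thermodynamic-Informational Entropic Relationship Simulations of
    Hierarchical Neural Workload and Population Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation framework linking information-processing work in a
    convergent hierarchical Hebbian network to irreversible thermodynamic
    entropy accumulation and structural failure. Provides the three-level
    columnar network with per-node work, informational-entropy and dynamic
    stability (Lyapunov) tracking across seeded Monte-Carlo ensembles; a
    deterministic coupled cortical/support "siphon" population-failure model
    governed by fracture-fatigue-entropy thresholds; stimulus generators
    (bounded random, equicorrelated Gaussian, sinusoidal); and a prespecified
    six-part sensitivity-analysis suite with reproducible sweep drivers and
    CSV/JSON reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
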