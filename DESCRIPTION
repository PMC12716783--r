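Package: hepsim
Title: Constrained Agent-Based Simulation of Paleolithic Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate gridded Human Existence Potential (HEP) from
    monthly paleoclimate fields and archaeological site records via an
    ensemble of quadratic logistic regressions, and to drive a constrained
    agent-based model of hunter-gatherer population dynamics on that
    landscape. Agents follow an Ornstein-Uhlenbeck velocity process with a
    macroscopic drift up the gradient of available HEP, reproduce and die
    under density-dependent Verhulst growth with an Allee-type mating-network
    term, and may admix where two populations co-occupy a grid cell. Includes
    a synthetic-landscape laboratory for parameter-recovery testing, ensemble
    machinery with multiplicative parameter perturbation, and diagnostics
    (population time series, rate-of-change maps, extinction fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
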