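Package: chemopursuit
Title: Agent-Based Simulation of Chemotactic Pursuit by a Searching Immune Cell
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a single chemotactically sensing immune cell pursuing
    multiple chemoattractant-emitting target cells on a two-dimensional plane
    with periodic boundary conditions. Target cells carry a stationary
    reaction-diffusion concentration kernel (fast-diffusion limit, solved by a
    shooting method); the immune cell is a correlated random walker whose
    migration mode and turning direction are modulated by logistic
    stimulus-response functions of temporal and spatial concentration
    differences. The package estimates search efficiency (eliminated targets
    per run) by Monte Carlo, optimizes strategy parameters by grid-based
    cyclic coordinate descent, and provides trajectory diagnostics (covered
    area, mean squared displacement, nearest-target-distance distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
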