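Package: asmca
Title: Whole-Cell Calcium Dynamics with Store-Operated Entry in Airway
    Smooth Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic whole-cell model of intracellular calcium
    dynamics in airway smooth muscle cells, coupling IP3-receptor-mediated
    store release (a Li-Rinzel/Tang reduction of the De Young-Keizer
    scheme) with slow store-operated calcium entry gated by SR depletion.
    Provides the flux terms and right-hand side, executable drug protocols
    (agonist, ryanodine-caffeine, the SERCA blocker CPA, external-calcium
    removal), stiff-solver simulation, equilibrium location with analytic
    Jacobians, Hopf-bifurcation and limit-cycle parameter sweeps with
    oscillation metrics, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
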