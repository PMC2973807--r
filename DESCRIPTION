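Package: neckstep
Title: Brownian Dynamics Simulation of Kinesin Stepping with Tethered
    Neck Linker Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates processive stepping of kinesin motors by coupling a
    discrete-state Markov chain for the chemomechanical hydrolysis cycle to
    overdamped Langevin (Brownian) dynamics of the tethered free motor head.
    Three mechanical representations of the neck linker tether are provided:
    a worm-like chain (increasing stiffness), a Hookean spring (constant
    stiffness, simulated with exact Ornstein-Uhlenbeck transitions), and a
    reflected diffusion between contour-length barriers integrated with a
    Lepingle-corrected Euler scheme.  Includes Boltzmann quadrature oracles
    for stationary head-position distributions, binding-zone occupancy and
    recurrence-time statistics, ensemble velocity and run-length summaries,
    and canned configurations for Kinesin-1 and a neck-linker-extended
    mutant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
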