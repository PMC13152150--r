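Package: mfcsim
Title: Multi-Stage Simulation Toolkit for Microbial Fuel Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation workflow for bench-scale microbial fuel cells (MFCs):
    Butler-Volmer electrode kinetics with per-material calibrated presets and
    polarization curves, Monod batch growth and substrate-depletion dynamics,
    a specified-conversion stoichiometric flowsheet (anode reactor, proton
    exchange membrane separator, cathode reactor) with element and charge
    balance checks, explicit finite-difference two-dimensional
    diffusion-reaction transport with a static biofilm zone, and seeded
    synthetic voltage datasets screened by one-way ANOVA with Fisher LSD
    post-hoc comparisons and a compact-letter material ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    nortest,
    car,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
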