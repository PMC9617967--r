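Package: mtkmc
Title: Kinetic Monte Carlo Simulation of Microtubule Growth with Tubulin
    Isotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic (first-reaction kinetic Monte Carlo) simulation of
    microtubule plus-end growth on a 13-protofilament lattice with a seam,
    built from three beta-tubulin dimer species (Tubb3, Tubb4 and a pooled
    class for the remaining isotypes) that differ in longitudinal and
    lateral bond free energies and free concentration.  Provides the rate
    laws linking bond energies to association and dissociation rates,
    cascade (stack) dissociation, growth-velocity and lattice-composition
    summaries, a grid search with velocity-window filtering to calibrate
    isotype bond energies against measured growth velocities, named
    concentration presets for control, Tubb3-knockdown and hypothetical
    expression scenarios, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
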