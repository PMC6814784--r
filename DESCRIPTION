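Package: aortasph
Title: Particle-Based Mechanics of Lamellar Damage in the Aortic Wall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Smoothed particle hydrodynamics (SPH) for nonlinear solids,
    specialized to a multi-layered model of the murine aortic wall. Builds
    quarter-sector particle lattices that resolve six elastic lamellae, five
    intra-lamellar smooth-muscle/collagen layers, and an adventitia; evaluates
    fiber-reinforced hyperelastic stresses with constituent deposition
    prestretches, parabolic smooth-muscle active tone, and Gibbs-Donnan
    osmotic swelling of glycosaminoglycan pools; relaxes to quasi-static
    equilibria by damped explicit dynamics with corrected kernel gradients and
    hourglass stabilization; and scripts lamellar-disruption and
    SMC-apoptosis/GAG-replacement damage scenarios, reporting bulk
    pressure-diameter behaviour and transmural stress concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
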