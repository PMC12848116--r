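Package: glassyclutch
Title: Glassy Motor-Clutch Simulation of Cell Migration on Viscoelastic Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic motor-clutch simulator of cell migration on viscoelastic
    (standard-linear-solid) substrates in which adhesion clutches draw their
    dissociation time constants from a heavy-tailed power law, producing glassy
    adhesion dynamics and anomalous (sub- and super-diffusive) migration.
    Includes Bell slip-bond kinetics, Hill-type myosin motors, a compiled
    per-timestep engine, single-particle trajectory statistics (mean squared
    displacement and its scaling exponent, velocity autocorrelation, track
    straightness, trap/step segmentation, kurtosis ratios), reference
    random-walk generators (ballistic, Brownian, CTRW, Levy walk), and scripted
    in-silico experiments (viscosity x glass-coefficient phase diagrams,
    fast-versus-slow relaxation contrasts, actomyosin-inhibition scenarios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
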