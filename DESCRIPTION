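Package: dwta
Title: Delayed Winner-Take-All Population Model of Perceptual Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a two-population winner-take-all
    rate model with delayed self-inhibition and multiplicative short-term
    plasticity. Provides deterministic (method-of-steps) and stochastic
    (Euler-Maruyama) integrators for the delay-differential system,
    evidence-accumulation psychometrics with a threshold decision rule,
    linear stability analysis of the symmetric resting state including the
    critical delay of the Hopf bifurcation, a Monte-Carlo success-rate
    experiment over noise magnitudes, and a Balloon-Windkessel hemodynamic
    forward model that turns the joint population signal into a synthetic
    BOLD series for variance predictions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
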