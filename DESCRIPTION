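Package: gmphets
Title: Growing Mixed Porohyperelasticity with Transport and Swelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Axisymmetric finite element simulation of growing, fully
    saturated porohyperelastic soft tissue with interstitial fluid flow and
    neutral-species transport (GMPHETS). Implements the multiplicative
    volumetric growth split with time-, concentration- and stress-driven
    growth laws, mass-source and porosity bookkeeping for solid-only and
    solid/fluid growth, Onsager (Darcy/Fick) transport in the deforming
    porous medium, mechano-chemical potentials as primary variables, a
    nested Newton-Raphson backward-Euler solver on linear axisymmetric
    triangles, closed-form validation solutions for a growing rigid
    cylinder, and preset arterial test scenarios with CSV/VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
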