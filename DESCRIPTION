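Package: esoflip
Title: Neuromechanical Simulation of Distension-Induced Esophageal Peristalsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organ-scale neuromechanical model of the smooth-muscle (distal)
    esophagus under sustained volumetric distension, as in functional lumen
    imaging probe (FLIP) panometry. A chain of unidirectionally coupled
    excitatory/inhibitory (Wilson-Cowan) relaxation oscillators is driven by
    distension-sensitive mechanoreceptors and coupled, through a muscle
    activation field, to a one-dimensional fluid-filled closed flexible tube.
    The package simulates the resulting spatiotemporal contraction patterns
    (repetitive antegrade contractions and their disorder-like perturbations),
    provides a library of named experimental scenarios, and classifies
    trajectories into the clinical pattern vocabulary (absent, antegrade,
    retrograde, synchronous, overlapping, sustained, disordered).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
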