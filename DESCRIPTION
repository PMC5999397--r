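Package: iceProfiler
Title: Characterization of Single-Particle CryoEM Grids from Tomograms
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterize single-particle cryoEM grid holes from
    cryo-electron tomograms: locate the two air-water interfaces, measure
    vitreous ice thickness and interface tilt, classify hole-region ice
    curvature, detect particles and assign them to interface layers,
    quantify adsorption, layer saturation and preferred orientation,
    compute CTF defocus-error resolution budgets for tilted fields of view
    and particle bilayers, aggregate grid-survey statistics with propagated
    measurement error, and recommend single-particle collection strategies.
    A synthetic grid-hole phantom generator with full ground truth makes
    every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CryoEM, Visualization, QualityControl, Software
RoxygenNote: 7.3.3
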