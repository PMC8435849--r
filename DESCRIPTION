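Package: optodefib
Title: Simulation of Optogenetic Defibrillation in Cardiac Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates optogenetic termination of reentrant cardiac
    arrhythmias in synthetic three-dimensional atrial- and ventricular-like
    tissue. Implements a two-state Markov photocurrent model of the anion
    channelrhodopsin GtACR1 and a four-state model of ChR2-H134R (plus a
    red-shifted variant), steady-state photon-diffusion light attenuation,
    human atrial (Courtemanche-type) and ventricular (ten Tusscher-type)
    myocyte kinetics, an opsin-coupled monodomain reaction-diffusion solver
    on structured grids with fiber rotation, arrhythmia induction by
    cross-field or rapid-pacing stimulation, and irradiance/timing
    defibrillation sweep protocols with outcome classification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
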