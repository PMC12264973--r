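Package: spvsim
Title: Simulated Prosthetic Vision with Raster-Scheduled Epiretinal Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A raster-scheduled simulated-prosthetic-vision (SPV) engine for
    epiretinal implants. Models a fovea-centered electrode array on the retina,
    phosphene shape through an axon-map spatial model (radial spread rho,
    axonal elongation lambda, combined by a maximum over the axon path),
    phosphene fading and persistence through two coupled leaky integrators,
    and charge-safety raster scheduling of electrode timing groups
    (horizontal, vertical, checkerboard, random). Includes generators for
    Sloan-style optotype and moving-bar stimuli, gaze-contingent rendering
    with synthetic gaze traces, a template-matching virtual observer for
    eight-alternative forced-choice tasks, and raster-quality metrics
    (apparent-motion index, motion-energy drift, confusion and bias analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
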