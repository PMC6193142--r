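Package: fibrilEM
Title: Single-Particle Averaging, Tomography and Morphometry of Beaded
    Microfibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multiscale structural analysis of beaded extracellular
    microfibrils imaged by electron microscopy.  Implements single-particle
    averaging and 3D reconstruction of the microfibril axial repeat from 2D
    negative-stain projections (phase-flip CTF correction, edge-mean
    normalization, top-hat band-pass filtering, masked normalized
    cross-correlation alignment, weighted back-projection, iterative
    projection-matching refinement with axial symmetry), region-masked
    sub-model refinement with rotational pseudo-symmetry detection, Fourier
    shell correlation resolution estimation, weighted back-projection of
    single-axis tilt series, and morphometry of filaments in tomograms
    (tracing, orientation, spacing, diameter, periodicity) and of fiber
    cross sections in serial-section stacks (ellipse minor-diameter
    measurement).  Ships synthetic phantom generators that emulate every
    input the pipeline consumes, with ground truth recorded for parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
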