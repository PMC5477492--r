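Package: fibremech
Title: Active Viscoelastic Mechanics and Image Quantification of Optogenetically Contracted Stress Fibres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an actively contracting viscoelastic cell under local
    RhoA-style activation (a 1D active Maxwell continuum frictionally coupled
    to an elastic substrate, and a 2D discrete viscoelastic cable network with
    stress-fibre force dipoles), synthesizes the corresponding microscopy
    observables (punctate fibre movies, traction-deformed bead images,
    focal-adhesion movies), quantifies them (traction force microscopy by
    regularized Fourier-transform traction cytometry, particle image
    velocimetry, variational optical flow, kymograph extraction and
    displacement-reversal analysis), and fits the continuum model to
    strain-energy traces and flow kymographs to recover the viscoelastic
    relaxation time that separates elastic-like from fluid-like stress fibres.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
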