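Package: mwtomo
Title: Microwave Tomography with a 2-D FDTD Forward Model and DBIM-TwIST Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and image reconstruction for antenna-ring microwave
    tomography of cylindrical phantoms in lossy immersion liquids. Provides
    single-pole Debye dispersion modelling and fitting, a 2-D TM-polarized
    finite-difference time-domain (FDTD) forward solver with
    auxiliary-differential-equation dispersion and convolutional PML
    boundaries, an analytic line-source/cylinder scattering oracle, a
    multistatic acquisition emulator with empty-tank calibration and receiver
    noise, and the distorted Born iterative method (DBIM) with frequency
    hopping solved by two-step iterative shrinkage-thresholding (TwIST) or
    conjugate-gradient least squares (CGLS).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
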