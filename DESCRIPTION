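Package: tracttf
Title: Volume-Velocity Transfer Functions of Tube-Like Acoustic Resonators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for obtaining the volume-velocity transfer function of
    tube-like acoustic resonators such as vocal-tract models from two
    external-excitation pressure measurements: the pressure at the closed
    glottal end with the mouth open (P1) and the pressure in front of the
    blocked mouth (P3). Implements the acoustic two-port (chain matrix)
    algebra that proves P1/P3 equals the volume-velocity transfer function
    U2/U1, plane-wave chain-matrix models of piecewise-cylindrical tubes
    with wall losses and side branches, piston-in-a-baffle radiation
    impedance, a first-order tetrahedral Helmholtz finite-element reference
    solver with impedance boundary conditions, exponential-sweep synthesis
    and deconvolution for virtual (or real) measurements, and formant,
    bandwidth and amplitude extraction with comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
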