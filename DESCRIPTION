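Package: flashxtal
Title: Dosimetry and Diffraction Physics for Femtosecond Serial Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of intense femtosecond X-ray pulses interacting
    with protein crystals and nanocrystals. Computes dose and fluence from
    tabulated atomic cross sections, one-photon-per-atom and hollow-atom dose
    scales, secondary-electron cascade and average-ionization dynamics,
    X-ray-driven atomic displacement under a plasma diffusion law, and the
    resulting pulse-gated Bragg and diffuse diffraction of small crystals,
    including Debye-Waller and random-ionization decompositions, dynamic
    disorder gating, and wavelength-scaling laws for maximizing Bragg signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
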