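Package: sfrsub
Title: Subdiffuse Scattering Model for Single Fiber Reflectance Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of single fiber reflectance (SFR)
    spectroscopy in the absence of absorption. The reflectance collected by a
    fiber that both delivers and detects light is modelled as the sum of a
    diffuse component (the Farrell pencil-beam solution integrated over the
    chord-length distribution of the fiber face) and a semiballistic component
    driven by the phase-function parameter psb, the backward integral of the
    phase function over 1 degree divided by one minus the forward integral
    over 23 degrees. Includes the Henyey-Greenstein, modified and two-term
    Henyey-Greenstein and Reynolds-McCormick (Gegenbauer kernel) phase-function
    families with Legendre-moment and sampling machinery, a compiled
    overlapping-fiber photon Monte Carlo with per-photon event tagging, the
    dispersion-minimisation experiment that selects the psb integration angles,
    calibration of the model constants against Monte Carlo ensembles, and a
    two-diameter (MDSFR) spectral inversion recovering the reduced scattering
    power law and psb per wavelength.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
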