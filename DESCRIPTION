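Package: tissueoptics
Title: Tissue Optical Property Estimation by Moment-Based Inversion of
    Time-Resolved Monte Carlo Photon Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates time-resolved photon transport through a homogeneous
    turbid slab (exponential free paths, Henyey-Greenstein anisotropic
    scattering, Beer-Lambert weight attenuation, Fresnel boundaries and
    Russian roulette), compresses the reflected photon cloud into the first
    orders of weighted spatio-temporal central moments, and trains a small
    fully connected neural network to recover the refractive index, reduced
    scattering coefficient and absorption coefficient from those moments.
    Includes dataset generation over the biologically relevant parameter
    ranges, model persistence, and accuracy evaluation via per-sample
    percentage errors and their 95% confidence level.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
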