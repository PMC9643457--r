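Package: layerfluence
Title: Photon Diffusion in Layered Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward solver for the photon diffusion equation in an N-layered
    turbid cylinder, as used in diffuse optical spectroscopy and time-domain
    near-infrared measurements of layered tissue (skin/fat/muscle, scalp/skull/
    brain). Computes steady-state fluence by a finite inverse Hankel transform
    over the zeros of the Bessel function J0, and time-resolved fluence by a
    numerical inverse Laplace transform along a hyperbolic Bromwich contour
    shared by all time points in a window. The spatial-frequency-domain Green's
    functions are evaluated in an overflow-free exponential form that remains
    finite for arbitrarily thick, highly scattering layers. Includes closed-form
    semi-infinite reference solutions, a fast source-term-resummed reflectance
    approximation, an arbitrary-precision computation path, and a layered
    Henyey-Greenstein Monte Carlo validator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    tibble
LinkingTo: Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
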