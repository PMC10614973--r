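Package: dogcsf
Title: Difference-of-Gaussians Shunting Model of Spatial Contrast Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates contrast-sensitivity functions of a one-dimensional,
    rate-based population of on-center/off-surround visual neurons. Receptive
    fields are modeled as a Difference of Gaussians whose excitatory and
    inhibitory subfields drive a shunting (membrane) equation; the closed-form
    equilibrium response to sinusoidal luminance gratings is swept across
    spatial frequency to produce model contrast-sensitivity curves. Includes
    curve-comparison statistics (cosine similarity, normalized difference
    index, band-wise paired tests), a catalog of excitation/inhibition
    manipulations reproducing published medicated/unmedicated schizophrenia
    sensitivity signatures, a numerical ODE oracle for the equilibrium, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
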