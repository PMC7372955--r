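Package: pbrflash
Title: Flashing-Light and Mixing Metrics for Tubular Photobioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Evaluates the flashing-light effect and mixing performance of
    tubular airlift photobioreactors from two-dimensional cross-sectional
    flow fields. Provides cross-section geometry models for plain,
    concentric double-tube and tangent double-tube reactors with light/dark
    zone partitioning; a calibrated synthetic generator for divergence-free
    velocity and turbulence fields built from streamfunction kernels;
    Lagrangian tracking of neutrally buoyant algal-cell surrogates under
    quadratic drag, pressure-gradient forcing and discrete-random-walk
    turbulent dispersion; and the evaluation metrics used to rank reactor
    designs: light/dark cycle frequency, light-time ratio, field-synergy
    angle statistics, averaged turbulent kinetic energy and dead-zone
    fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
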