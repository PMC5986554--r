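Package: aggkin
Title: Autocatalytic Kinetics and Morphometry of Amyloid-Beta Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic analysis of amyloid-beta(1-42) fibrillation with the
    two-step autocatalytic nucleation-elongation model. Provides the
    closed-form sigmoidal fibril-fraction solution and an independent ODE
    oracle, nonlinear least-squares fitting of thioflavin-T fluorescence
    time courses to extract nucleation (kn) and elongation (ke) rate
    constants, pairwise fold-change comparison of constants across membrane
    conditions, joint length-height classification of AFM particle
    measurements into protofibril and fibril species, and seeded synthetic
    generators for both data modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
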