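Package: reefmetab
Title: Benthic Primary Production from Incubation O2 Fluxes with Bayesian
    Model-Averaged Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for coral-reef benthic primary production
    estimated from short-term light/dark incubations. Converts paired oxygen
    concentration measurements into blank-corrected net production,
    respiration and gross production per unit 3D specimen surface; estimates
    benthic cover from line-point-intercept transects, rugosity from chain
    measurements, and 2D-to-3D surface conversion factors from paired areas;
    upscales organism fluxes to seafloor-area contributions and daily
    ecosystem production under a 12 h light / 12 h dark cycle; and fits
    Gaussian linear models by conjugate Gibbs sampling with DIC-based model
    averaging, highest-posterior-density intervals and posterior pairwise
    comparisons. Includes a synthetic-data generator that emulates every
    input table so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
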