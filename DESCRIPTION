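Package: spinepinn
Title: Hybrid Finite-Element and Physics-Informed Neural-Network
    Estimation of Lumbar Spine Material Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inverse identification of isotropic elastic
    material properties (Young's modulus, Poisson's ratio, bulk and shear
    modulus, density) of vertebral bone and intervertebral discs from
    simulated mechanical responses. Provides a synthetic lumbar-spine
    phantom generator with conforming vertebra/disc tetrahedral meshes and
    geometric endplate annotation, a linear-elastic four-node tetrahedron
    finite-element solver for prescribed-displacement compression, a
    training-data builder that sweeps material properties and load
    magnitudes, a multilayer-perceptron regressor trained with a
    physics-informed loss that penalises violations of the isotropic
    elasticity identities, and an iterative finite-element/network
    fixed-point calibration loop with contraction-ratio diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
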