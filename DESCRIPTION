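Package: bayesnav
Title: Bayesian Ideal Observer for Spatial Navigation Under Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-computable Bayesian ideal observer of navigation in
    polygonal enclosures. Simulates noisy pose dynamics and egocentric
    sensing (a pinhole-rendered retina with Poisson noise, plus optional
    tactile probes), performs grid-based recursive Bayesian filtering over
    pose -- including mismatch between the true and the believed
    environment -- and drives homing and distance-estimation policies from
    the resulting posteriors. Provides Fisher-information analysis of
    visual location information, a warped grid-cell population code fitted
    so that a decoded neural posterior matches the ideal observer's
    posterior, and the grid-field metrics (gridness, scale, field
    diameter, axis scaling ratio, phase shift, tethering-versus-scaling
    correlation) used to characterise deformation, rescaling and boundary
    tethering of grid fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
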