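Package: follicleRD
Title: Spatio-Temporal Reaction-Diffusion Model of Bovine Ovarian Follicle Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hormone and receptor signalling in the growing bovine
    ovarian follicle as an eleven-species reaction-diffusion system on a
    uniformly expanding one-dimensional cross-section with theca, granulosa,
    cumulus-oocyte-complex and follicular-fluid compartments. Ships the full
    literature-derived parameter set with unit-conversion helpers, solves the
    stiff method-of-lines system with zero-flux boundaries, reduces solutions
    to compartment-averaged time courses, gradients, production and
    receptor-activity fields, and quantifies robustness to multiplicative
    Gaussian parameter noise via ensemble simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
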