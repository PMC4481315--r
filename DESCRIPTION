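Package: gazeflight
Title: Head-Saccade, Wingbeat-Mode and Landing-Cue Analysis for Maneuvering
    Bird Flight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-speed kinematic recordings of small
    birds performing rapid U-turn flight maneuvers in an arena. Provides
    penalized least-squares (Whittaker) smoothing with leave-one-out
    cross-validation error, head and body yaw computation from 3-D marker
    pairs, angular-velocity-threshold head-saccade detection and statistics,
    two-component Gaussian-mixture classification of intermittent versus
    normal wingbeat modes, azimuthal arena-feature stabilization
    distributions, and optical landing-cue (retinal size, expansion rate,
    RREV, tau) coefficient-of-variation parsimony analysis. A synthetic
    trial generator with known ground truth supports parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pracma,
    jsonlite
Config/testthat/edition: 3
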