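Package: nanoqspr
Title: Nano-QSPR Modeling of Nanoparticle Zeta Potential by GA-PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-property (nano-QSPR) modeling of the
    zeta potential of polymeric nanoparticles from block-structured
    descriptor tables covering the particle core, its surface coating, and
    binary protein-corona fingerprints.  Implements NIPALS partial
    least-squares (PLS1) regression with per-component variance accounting,
    autoscaling with training-set parameters, leave-one-out cross-validation
    with honest per-fold rescaling, external validation statistics,
    leverage-based applicability-domain diagnostics (Williams plot),
    genetic-algorithm descriptor selection, nested descriptor-domain
    comparison, and a synthetic descriptor-table generator.  Ships a
    published benchmark dataset of 20 polymeric nanoparticles with five
    selected descriptors and measured zeta potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
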