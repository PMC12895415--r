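Package: zindoml
Title: Delta Machine Learning of TDDFT Excited-State Energies from ZINDO
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Corrects semiempirical ZINDO first-singlet (S1) excitation
    energies toward TDDFT quality with a residual ("delta") machine
    learning model ensemble. Provides electronically informed molecular
    descriptors (molecular-orbital-weighted radial distribution
    functions, atomic potentials, Mulliken charges, natural-transition-
    orbital particle/hole densities), an attention-based message-passing
    encoder with dense embedding blocks and a residual connection on the
    ZINDO energy, k-fold ensemble training, dataset-curation operators
    (conjugated-core clustering, candidate filters, core-analogue test
    sampling, parity splits), evaluation utilities including
    visible-range screening and oscillator-strength classification, and
    a synthetic-data generator so the full pipeline is testable without
    quantum chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
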