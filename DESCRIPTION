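Package: crisprdyn
Title: Chemostat Population Dynamics of CRISPR-Mediated Immunity to Phage and Plasmids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic chemostat models of the ecological conditions under
    which CRISPR-mediated adaptive immunity is established and maintained in
    bacterial populations. Implements a lytic-phage model (sensitive,
    envelope-resistant, CRISPR and immune-CRISPR cells with a multiplicity-of-
    infection-dependent override of immunity) and a conjugative-plasmid model
    (mass-action conjugation, vegetative segregation, immunity acquisition and
    loss), together with closed-form invasion and maintenance thresholds, an
    immune-culture phage-decline curve, named scenario presets, an ecological
    outcome classifier, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
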