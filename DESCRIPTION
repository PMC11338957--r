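Package: rsbuffer
Title: Releasing-Shuttling Model of mRNA Concentration Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic modelling of mRNA buffering through the
    releasing-shuttling (RS) mechanism, in which a degradation factor X and an
    export factor Y are released from the preinitiation complex at every
    transcription initiation and convey the production rate downstream to
    mRNA export and decay. Provides the seven-state ODE core with a
    conservation-aware steady-state solver, model variants (feedback-only
    null models, non-essential X, shuttling Y, nuclear exosome, transcriptional
    drop-off, mRNA imprinting, PABPC1/host-shutoff, and a two-group model),
    seeded in-silico perturbation screens and acute-depletion protocols, a
    staged nonlinear least-squares parameter-estimation pipeline for
    fold-change time courses, readers for perturbation-screen and time-course
    tables, and synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
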