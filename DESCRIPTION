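Package: mapkrewire
Title: Retargeted MAPK Degradation Circuits: Simulation, Cytometry
    Processing and Dose-Response Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying synthetic kinase-substrate rewiring in
    which a MAP kinase (yeast Fus3 or human ERK2) is redirected, via
    modular interaction domains and phosphodegrons, to degrade an
    arbitrary reporter substrate. Provides a seeded event-level flow
    cytometry simulator (log-normal cell size and protein concentration,
    instrument dialects), the standard event-processing pipeline
    (zero/offset correction, forward-scatter size normalization,
    anomaly gating, population summaries), steady-state Hill and
    incoherent feed-forward (band-pass) dose-response models with
    shared-parameter nonlinear least-squares fitting and bootstrap
    uncertainty, and a mechanistic ODE model of kinase-directed,
    ubiquitin-mediated substrate degradation with scenario switches for
    the standard control strains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
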