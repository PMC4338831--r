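Package: xenodyn
Title: Kinetic Simulation of Cellular Xenobiotic Detoxification with
    Toxicodynamic Fitness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic reaction-kinetic simulation of the cellular
    "chemoimmune" xenobiotic defense network: Phase 0 and Phase III ABC
    efflux transporters, Phase I oxidation (CYP), Phase II conjugation
    (GST), and their transcriptional regulation through a xenobiotic
    nuclear receptor and the Keap1-Nrf2 oxidative stress pathway. Models
    are built in code or exchanged as SBML Level 2 Version 4 documents
    (compartments, species, parameters, kinetic laws, assignment and rate
    rules, events). Time courses are integrated with a stiff-capable
    solver after steady-state pre-equilibration, and a cellular-fitness
    toxicodynamic layer (chemical load, damage, regeneration, death)
    supports in silico cytotoxicity assays with EC50 extraction,
    parameter scans and scripted dose-response scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
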