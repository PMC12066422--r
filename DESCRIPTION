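Package: asipbpk
Title: Whole-Body PBPK and Emax Pharmacodynamic Simulation of Aldosterone
    Synthase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK)
    simulator for orally dosed aldosterone synthase inhibitors (ASIs),
    coupled to an Emax inhibition pharmacodynamic layer for aldosterone
    synthase (CYP11B2) and 11beta-hydroxylase (CYP11B1). Fourteen
    perfusion-limited tissue compartments plus arterial and mixed venous
    blood are integrated as a linear ODE system with first-order
    gastrointestinal absorption and systemic clearance. Includes a
    reference adult physiology, a five-compound ASI parameter library,
    ADME parameter-derivation helpers, partition-coefficient calibration
    by grid search, non-compartmental analysis (AUC, Cmax, Tmax, terminal
    half-life, fit metrics), selectivity indices, and single/multiple
    ascending dose study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    pracma,
    yaml,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'asipbpk-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'compound.R'
    'library.R'
    'physiology.R'
    'pbpk.R'
    'nca.R'
    'pd.R'
    'study.R'
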