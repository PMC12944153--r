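Package: fluvopbpk
Title: Population Pharmacokinetic Simulation of Fluvoxamine by CYP2D6
    Phenotype and Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minimal physiologically based pharmacokinetic (PBPK) simulator for
    fluvoxamine in virtual younger-adult and geriatric populations stratified by
    CYP2D6 metabolizer phenotype (PM, IM, EM, UM). Scales in vitro CYP2D6 enzyme
    kinetics to whole-body clearance (IVIVE with a well-stirred liver), integrates
    a minimal PBPK distribution model under single- and multiple-dose oral
    regimens, and summarizes exposure (Cmax, Cmin, AUC) against the fluvoxamine
    therapeutic range. The central fitting function calibrates the unknown
    non-CYP2D6 clearance and a geriatric activity scalar against published
    clinical anchors and returns a model object with simulate, predict and plot
    methods for verification, age-comparison and phenotype-stratified dosing
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
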