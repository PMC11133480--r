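Package: cxtrial
Title: CXCL12 Aptamer Trial Analytics: mIF Phenotyping, EG12 Biomarker,
    mRANO Response and Survival Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the computational analyses of a
    radiotherapy plus CXCL12-neutralizing aptamer (NOX-A12) glioblastoma
    dose-escalation trial: phenotype gating of segmented multiplexed
    immunofluorescence cell tables with CXCL12-positivity frequency
    profiles (E12/P12/M12/G12), the composite median-centered EG12
    biomarker with Spearman correlation against progression-free
    survival, a modified RANO (mRANO) lesion response engine with
    confirmation logic and PFS/OS event derivation, Kaplan-Meier,
    log-rank, Cox, Mann-Whitney and adverse-event summary statistics,
    modified 3+3 dose-escalation decisions, and a synthetic-cohort
    generator that emulates the statistical structure every stage
    assumes so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
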