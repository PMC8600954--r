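Package: mbdx
Title: Centralised Medulloblastoma Molecular Diagnostics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline modelling a national centralised
    molecular-diagnostics pathway for medulloblastoma. Generates seeded synthetic
    cohorts with subgroup-structured DNA-methylation and expression profiles,
    applies specimen quality-control gates, assigns molecular subgroups (WNT, SHH,
    Group3, Group4) by rank-4 non-negative matrix factorisation metagenes and a
    support vector machine with bootstrap-resampling confidence, calls MYC/MYCN
    amplification on three platforms (iFISH, MLPA, methylation-array) and
    chromosome-6 monosomy, integrates multi-assay WNT consensus and pathologist
    review, benchmarks assays by sensitivity/specificity, and applies WHO-2016
    classification and SIOP-PNET5-MB eligibility rules with turnaround-time
    accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
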