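Package: pvsignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance analyses of FAERS-style spontaneous
    report databases: ingestion of the quarterly '$'-delimited ASCII tables,
    FDA-recommended case de-duplication, SMQ-based case definition restricted
    to Primary-Suspect drugs, four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio with chi-square, BCPNN
    information component, and the DuMouchel gamma-Poisson shrinker EBGM)
    combined under a joint positivity rule, demographic stratification with
    Bonferroni adjustment, IC025 risk tiers, Weibull time-to-onset modelling
    with rank-sum group comparisons, and a seeded synthetic report generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    fitdistrplus,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
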