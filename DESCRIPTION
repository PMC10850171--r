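Package: oaapflow
Title: Treatment Patterns, Adherence and Costs for Oral Antipsychotics from Administrative Claims
Version: 0.1.0
Authors@R:
    person("TxCORE", "Replication Engineering", email = "oaapflow@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for claims-based
    pharmacoepidemiology of oral atypical antipsychotic (OAAP) therapy in a
    Medicaid-like population with schizophrenia. Provides a seeded synthetic
    claims generator with per-patient ground truth, incident-user cohort
    selection with an ordered attrition ledger, hospitalization-adjusted
    proportion-of-days-covered (PDC) adherence, switch and augmentation
    classification, the Quan ICD-10 Charlson comorbidity index, all-cause and
    schizophrenia-related utilization and expenditure aggregation, and the
    group-comparison tables (chi-square, Mann-Whitney-Wilcoxon,
    Kruskal-Wallis) that typically accompany such analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    IRanges,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
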