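Package: arnfkb
Title: Signature Scoring, Enrichment and Survival Analysis of AR/NF-kB
    Transcriptional Programs in Tumor Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking androgen-receptor (AR) and NF-kB
    transcriptional programs in tumor expression data: microarray chip
    quality control by 1.5-IQR fences on relative log expression, summed
    Z-score signature scoring against a normal-tissue reference, tumor
    stratification by extreme signature scores or dual GSK3A/GSK3B
    thresholds, weighted running-sum gene-set enrichment with a
    phenotype-permutation null, derivation of repressed-target gene sets
    from negative leading edges, Kaplan-Meier/log-rank survival analysis
    of signature-defined groups, and quantitation of protein/DNA
    binding-array membranes and delta-delta-Ct qPCR tables. Ships a
    synthetic cohort generator that emulates anticorrelated AR/NF-kB
    programs, GSK3-coupled expression, planted outlier chips and
    signature-dependent hazards, so every stage is testable without
    external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
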