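Package: clozanc
Title: Local-Ancestry-Aware Association and Risk Prediction for
    Clozapine-Induced Neutropenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control analysis pipeline for a candidate pharmacogenetic
    variant underlying clozapine-induced neutropenia and agranulocytosis.
    Provides genotype hard-calling from posterior probabilities, variant QC
    (missingness, minor allele frequency, Hardy-Weinberg exact test),
    phenotype definition from absolute neutrophil counts, local-ancestry
    dosage summarisation with permutation group comparisons,
    covariate-adjusted single-variant logistic association with an
    ANC-threshold sweep and weighted trend line, and prevalence-recalibrated
    predictive test characteristics combining genotype with local-ancestry
    estimates. Includes a synthetic admixed-cohort generator emulating the
    statistical structure these analyses assume, so every stage is testable
    without consortium-held data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
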