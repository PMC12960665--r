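Package: gnbstriage
Title: Semi-Automated Variant Triage for Genomic Newborn Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for panel-restricted genomic newborn
    screening (gNBS): gene-condition panel management, ingestion of
    annotated VCF and targeted-caller calls with per-sample sequencing QC,
    technical-artefact exclusion, mode-of-inheritance-aware preset
    prioritisation, automated case triage into 'low chance' and 'for
    review', curation-driven reporting of 'high chance' and 'low chance'
    screening results, and screening-performance evaluation with exact
    binomial (Clopper-Pearson) confidence intervals. Includes a
    deterministic synthetic-cohort generator emulating a 46-case
    validation cohort and prospective edge-case archetypes so the whole
    workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
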