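Package: clonarch
Title: Clonal Architecture Analysis for CMML Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the clonal architecture of chronic
    myelomonocytic leukemia (CMML) and its transformation to secondary AML
    from targeted and whole-exome sequencing summaries. Implements somatic
    variant classification against a tumor-contaminated matched normal
    (exact Fisher rule), read-support, population-frequency and
    panel-of-normals filters, driver annotation, driver-timing
    categorization across paired chronic-phase/transformed samples,
    VAF-based clonality calling with ROC-derived cutoffs, clone ordering
    from single-colony genotypes, natively implemented survival and
    association statistics (Kaplan-Meier, log-rank, Cox proportional
    hazards, L1-regularized logistic regression), ChIP-qPCR fold-enrichment
    arithmetic, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    pROC,
    withr
Config/testthat/edition: 3
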