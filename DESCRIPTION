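Package: omicstrata
Title: Integrative Multi-Omics Subtyping of Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for integrative
    genomic/epigenomic/transcriptomic subtyping of tumor cohorts: copy-number
    segment merging and gene-level mapping, methylation probe filtering with
    KNN imputation and promoter aggregation, per-sample CNV/methylation event
    concordance statistics, Fisher-z correlation screening of copy-number- and
    methylation-driven gene sets, single-omics consensus subtyping by
    non-negative matrix factorization with cophenetic rank selection,
    multi-omics subtyping by a lasso-penalized Gaussian latent-variable model,
    and downstream subtype characterization (exact contingency tests,
    negative-binomial Wald differential expression, Kaplan-Meier and log-rank
    survival stratification, rank tests, hypergeometric enrichment). Includes
    a coupled multi-omics simulator that plants subtypes, dosage couplings,
    event-burden correlation and survival structure so that every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
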