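Package: tatscreen
Title: Tumour-Associated T Cell Screening from TCR Repertoires and
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies circulating tumour-associated T cells (TATs) as
    peripheral-blood T-cell clones whose CDR3 beta sequences are shared
    with tumour-infiltrating lymphocytes from the same patient, and builds
    a non-invasive cancer screening score from them. Provides readers for
    AIRR and immunoSEQ-style repertoire tables, four-compartment
    PBMC/TIL overlap analysis, repertoire diversity statistics (Shannon
    entropy, clonality, Gini coefficient), a one-hot-encoded
    convolutional neural network classifier of TAT-like CDR3 sequences
    with patient-level cross-validation and positional motif enrichment,
    a TCR repertoire risk score (TRRS), recurrent differential-expression
    signature derivation and scoring across single-cell datasets with
    leave-one-dataset-out validation, a tumour immunogenicity score, and
    a combined logistic screening model. A synthetic-data module
    generates paired repertoires, healthy sequence pools, labelled
    cohorts and expression matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
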