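Package: mrxome
Title: Two-Sample Mendelian Randomization with Transcriptomic Risk Scoring
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline from GWAS and QTL summary statistics to
    transcriptomic risk scores. Implements instrument selection and
    harmonization for two-sample Mendelian randomization (LD clumping,
    F-statistic filtering, removal of outcome-associated variants),
    causal estimators and pleiotropy diagnostics (Wald ratio,
    inverse-variance weighting, MR-Egger, Cochran's Q, MR-PRESSO,
    leave-one-out), per-gene eQTL/pQTL screens that classify risk and
    protective genes by odds ratio, single-sample GSEA risk scores with
    rank-based group comparison, mutual-information regulon inference
    with permutation, bootstrap and data-processing-inequality pruning,
    signature-based immune-cell scoring with spillover compensation and
    sparse (LASSO) selection, and a synthetic-data generator so every
    stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
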