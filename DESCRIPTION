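Package: tolsig
Title: Immunosuppression-Independent Gene-Expression Signatures of
    Transplant Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and evaluating gene-expression signatures of
    kidney-transplant operational tolerance that are not confounded by the
    immunosuppressive drug regimen. Implements per-gene linear drug-effect
    models on treated patients and the resulting immunosuppression-independent
    expression (IS-IE) residualization, elastic-net penalized logistic
    signature selection with leave-group-out resampling and a gene cap,
    confounding-adjusted classifier evaluation (drug-association tests,
    residual-adjusted AUC, paired Wilcoxon and McNemar stability), maxmean
    gene-set analysis with restandardization and permutation FDR, delta-Ct
    normalization and background filtering for RT-qPCR panels, and a synthetic
    cohort generator that emulates the group/drug structure of tolerance
    studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
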