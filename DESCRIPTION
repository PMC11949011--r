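Package: erpredict
Title: Multimodal Early Response Prediction from Liquid Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Early response prediction to immune checkpoint inhibition in
    metastatic urothelial cancer from paired baseline and on-treatment liquid
    biopsies. Quantifies circulating tumor DNA (variant filtering, dependent
    calling against control and white-blood-cell samples, copy-number-aware
    tumor-fraction estimation, copies-per-mL conversion with exact binomial
    uncertainty limits) and dichotomizes its longitudinal dynamics; runs
    paired and group differential expression on whole-blood RNA counts with
    TMM normalization and empirical-Bayes moderated t statistics; trains a
    sparse partial-least-squares discriminant classifier with repeated
    stratified cross-validation; and arbitrates the two modalities through
    uncertainty bands around their decision cutoffs. Includes a synthetic
    cohort generator emulating the paired study design, Kaplan-Meier and
    log-rank survival stratification, and an end-to-end pipeline with strict
    discovery/test/validation cohort separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    Matrix,
    optparse
Config/testthat/edition: 3
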