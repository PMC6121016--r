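Package: DECtp
Title: Differential Expression Calling Between Tumor and Normal Samples
    Accounting for Tumor Purity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls differentially expressed genes between tumor and normal
    samples while correcting for tumor purity. Observed tumor expression is
    modeled as a purity-weighted mixture of normal and pure-tumor signal; a
    per-gene linear model with a purity design column is fit by least squares,
    group-wise residual variances are stabilized by shrinkage toward their
    geometric mean, and the pure-tumor effect is tested with a Wald statistic
    referred to a t distribution, with Benjamini-Hochberg FDR control. Includes
    a simulation framework generating purity-confounded datasets with known
    differential-expression truth, an ROC/AUC evaluation harness against a
    two-sample t-test baseline, and diagnostics quantifying the correlation
    between gene expression and tumor purity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    optparse
Config/testthat/edition: 3
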