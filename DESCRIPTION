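Package: pgxagree
Title: Agreement Assessment for Paired Pharmacogenomic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to assess agreement between two independently generated
    cell-line drug-screening studies. Harmonizes and intersects sensitivity
    (AUC, IC50) and molecular-profile (expression, copy number, mutation)
    matrices onto common cell lines, drugs and genes; binarizes drug response
    by the waterfall inflection-point method or fixed cutoffs; computes
    per-drug and per-gene consistency statistics (Pearson correlation,
    Cohen's kappa) against standard agreement thresholds; and quantifies, by
    simulation on a paired-study generator with controlled reliability, how
    analysis designs that share genomic data between studies or compare
    mismatched sensitivity measures inflate apparent biomarker concordance
    relative to a fully independent comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
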