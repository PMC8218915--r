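Package: frlselect
Title: Integrative Feature Selection for Biomarker Discovery via Fisher
    Score Filtering and Recursive Feature Elimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage supervised feature selection for labelled gene
    expression matrices. A fast filter layer ranks genes by Fisher score
    and cuts the ranking at an automatically detected inflection point;
    an embedded layer then applies recursive feature elimination wrapped
    around a from-scratch logistic regression classifier under stratified
    K-fold cross-validation, with an elimination pace keyed to the
    post-filter dimensionality. Selections from repeated runs or multiple
    datasets are aggregated by pairwise-intersection consensus into a
    candidate biomarker module. Includes readers for tab-delimited and
    GEO series-matrix expression files, probe-to-gene collapsing,
    confusion-matrix/ROC/precision-recall evaluation with Euclidean
    distance clustering for heatmaps, and a seeded synthetic-data
    generator with planted differential genes for validation at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    pheatmap
Config/testthat/edition: 3
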