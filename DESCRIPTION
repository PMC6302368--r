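Package: mdsn
Title: MiRNA Dysregulational Synergism Networks for Module Discovery and
    Stage Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects changes in miRNA-target Pearson correlations between
    sample subgroups (dysregulations) with a Fisher z-test, assembles a
    binary miRNA-by-(target, analysis) association matrix, builds a
    weighted miRNA-miRNA synergism network from cosine similarity of
    shared dysregulated targets, prunes it with a scale-free hard
    threshold, extracts miRNA modules by Louvain modularity clustering,
    and uses the modules as group structure in a sparse group lasso
    logistic classifier for phenotype or stage prediction and biomarker
    ranking. Includes a synthetic cohort generator with planted
    dysregulation modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
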