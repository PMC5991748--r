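Package: mirmod
Title: miRNA Co-Expression Module Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discovery and evaluation of miRNA co-expression module biomarkers
    from case, technical-replicate and control expression cohorts. Builds
    weighted co-expression networks (soft-thresholded adjacency, topological
    overlap, dendrogram module detection), compares partitions across cohorts
    with Fisher overlap tests and the module-based consensus ratio, scores
    module preservation and activation with a permutation Z_summary statistic,
    ranks hub miRNAs with a network-constrained linear support vector machine,
    evaluates weighted module scores as diagnostic markers (ROC, AUC, Youden
    cutoff, subset search), and derives consensus target genes with
    hypergeometric term enrichment. A synthetic three-cohort generator with
    known module structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    kernlab,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
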