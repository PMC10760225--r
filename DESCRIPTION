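Package: hplkit
Title: Histomorphological Phenotype Learning for Biopsy Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested reimplementation of the
    histomorphological phenotype learning (HPL) workflow for prognosis from
    biopsy whole-slide images: tile tessellation with background filtering and
    Reinhard colour normalisation, a self-supervised Barlow-Twins tile encoder,
    Leiden community detection over tile-embedding kNN graphs (including an
    over-clustering artifact pass), compositional slide and patient vectors
    with the centred log-ratio transform, cross-validated elastic-net logistic
    and Cox survival models with median-split risk stratification, and
    interpretation statistics (linear SHAP, forest summaries, Spearman
    enrichment, tile-adjacency interaction matrices). Ships a synthetic
    multi-institution cohort generator with planted phenotypes and
    proportional-hazards outcomes so the whole pipeline is testable without
    access to clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
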