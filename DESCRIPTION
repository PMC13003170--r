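Package: recland
Title: Recombination Landscape Mapping and Multi-Omic Prediction for
    Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds binned meiotic recombination maps from crossover
    intervals detected in large multiparental populations, integrates
    per-bin multi-omic features (DNA methylation by context, transposable
    element and gene coverage, chromatin accessibility, expression,
    nucleotide composition, telomere distance, subgenome identity),
    defines recombination hotspots, and fits predictive models under a
    homoeolog-grouped cross-validation protocol designed for
    allopolyploid genomes such as Brassica napus.  Includes a
    multicollinearity-robustness protocol for model selection, from-
    scratch accumulated local effects and Friedman H-statistics for
    model interpretation, and a synthetic-data generator that emulates
    the statistical structure of a two-subgenome recombination study for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    lhs,
    glmnet,
    ranger,
    rpart,
    xgboost,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
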