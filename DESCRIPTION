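Package: devtraj
Title: Comparative Developmental Transcriptome Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of developmental gene expression
    time courses across species. Implements detection of stage demarcation
    points by hierarchical clustering of samples, dynamic network biomarker
    (DNB) critical-transition detection with a sliding-window composite index,
    early-versus-late differential expression with cell-type marker derivation
    and Fisher's exact gene-set enrichment, dynamic-time-warping estimation of
    expression heterochrony (acceleration versus neoteny) between species, and
    co-expression module analysis with modular differential connectivity and
    mutual-information key-driver identification. A synthetic-data generator
    produces two-species developmental expression datasets with planted ground
    truth so every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
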