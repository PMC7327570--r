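Package: sigfunnel
Title: Multi-Stage Feature-Selection Funnel for Multi-Class Transcriptome Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers compact gene-expression signatures that discriminate
    several sample classes at once, following a staged funnel: quantile
    normalization of multi-platform expression matrices, Boruta all-relevant
    filtering against permuted shadow features, Monte-Carlo Feature Selection
    (MCFS) ranking by relative importance aggregated over ensembles of
    projection trees, incremental feature selection (IFS) scored by
    support-vector-machine leave-one-out cross-validation, and hypergeometric
    over-representation analysis of the final signature against user-supplied
    gene-set collections.  Includes a synthetic-data generator with planted
    discriminating genes and platform batch structure so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
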