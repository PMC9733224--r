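Package: netpersist
Title: Longitudinal Signed Co-Occurrence Networks and Persistence for
    Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers one signed, sparse microbial co-occurrence network per
    (time point, condition) stratum from compositional amplicon count
    tables, using the centered log-ratio transform, Meinshausen-Buhlmann
    neighborhood selection over a regularization path, and StARS stability
    selection.  Classifies node and signed-edge persistence across
    consecutive time-point networks (stable versus transient, and
    whole-experiment transit), compares conditions, and ships a
    logistic-normal-multinomial simulator with planted precision matrices
    and controlled node/edge turnover for ground-truth validation of the
    full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    biomformat,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
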