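Package: switchscan
Title: Genome-Scale Mining of Bistable Gene Switches from Expression Compendia
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene switches (bistable, all-or-none expression programs) in
    large gene-expression compendia. Each gene's profile is scored for bimodality
    with the AIC difference between one- and two-component Gaussian fits (delta
    AIC), screened against a target phenotype with the separation statistic D,
    validated on an independent paired dataset, and classified into switch types
    by mixture-mode occupancy. Entropy-based information gain quantifies how well
    a discretized gene predicts a phenotype, and hypergeometric mode enrichment
    links expression modes to condition categories. Bundled ODE simulators of
    bistable gene circuits (a self-activating switch and a mutual-repression
    toggle) generate synthetic compendia with planted switches, so every stage of
    the pipeline can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
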