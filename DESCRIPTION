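Package: streamhyb
Title: Hybrid-Zone Introgression Modeling on Dendritic Stream Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models threshold exceedance of rainbow-trout introgression in
    westslope cutthroat trout populations across dendritic stream networks.
    Provides network trimming rules, along-network propagule-proximity
    covariates, iteratively reweighted least squares logistic regression
    with exhaustive AIC subset selection and a cross-threshold consensus
    rule, ROC/threshold/cross-validation evaluation, climate-warming and
    introgression-equilibrium scenario projection with habitat length and
    volume accounting, and a seeded synthetic riverscape and
    diagnostic-marker genotype simulator so the full pipeline runs without
    external data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
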