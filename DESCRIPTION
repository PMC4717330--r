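Package: msmark
Title: Multistate Mark-Recapture Models of Survival and Breeding Dispersal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits two-state Arnason-Schwarz multistate mark-recapture models
    to encounter histories of marked animals, estimating apparent survival,
    recapture, and between-habitat movement probabilities on the logit scale
    with covariate effects. Supports QAICc model selection with Akaike
    weights, model averaging with unconditional standard errors, a stepwise
    annual-covariate selection procedure, parametric-bootstrap estimation of
    the overdispersion factor c-hat, MARK-style '.inp' input files, and a
    seeded simulator of staggered-entry encounter histories for power and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
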