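Package: popcodewm
Title: Neural Population-Coding Models of Visual Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates and fits a neural resource (population coding) model
    of visual working memory for continuous-report tasks. Stimuli are encoded
    as Poisson spiking of tuned neural populations whose total activity is
    normalized across memory load, and decoded either by maximum likelihood
    or by sampling from the Bayesian posterior. Supports circular feature
    spaces (grating orientation) and bounded linear spaces (facial-expression
    intensity), Monte-Carlo prediction of binned response distributions,
    grid-search maximum-likelihood fitting with AIC model comparison,
    circular and Euclidean descriptive error statistics, and generators for
    balanced synthetic continuous-report experiments with mixed face and
    grating arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
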