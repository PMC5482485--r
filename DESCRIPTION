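Package: gndm
Title: General Nominal Diagnosis Models for Situational Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Design and estimation tools for diagnostic classification of
    typical-performance constructs measured with situational items and
    nominal response options.  Implements the saturated general nominal
    diagnosis model (GNDM) with an extended Q-matrix that codes every
    response option (including none-of-the-above options), marginal
    maximum likelihood estimation by EM, standard errors from the item
    information matrix, collapsed pattern-expected (PEDM) and
    option-expected (OEDM) reduced summaries with delta-method standard
    errors, likelihood-ratio model comparison, absolute fit assessment
    through simulated-predicted log-odds-ratio residuals, and a
    simulation harness for classification-accuracy and
    parameter-recovery studies with correlated dichotomous attributes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
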