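Package: gridlogit
Title: Federated (Grid) Ordinal and Multinomial Logistic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of proportional-odds (cumulative logit)
    and multinomial logistic regression models across multiple data sites that
    exchange only aggregate quantities (log-likelihood values, gradients and
    Hessian matrices), never observation-level records. The grid Newton
    iteration is algebraically identical to the centralized fit on pooled data.
    Includes the grid score test of the proportional-odds assumption against
    the generalized ordered logit alternative, Hosmer-Lemeshow and extended
    Hosmer-Lemeshow goodness-of-fit tests, rank-sum binary AUC, the Hand-Till
    generalized AUC and the ordinal mean-AUC, a simulation harness for
    multi-site study designs, and preprocessing recipes for the low birth
    weight and mammography-experience worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
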