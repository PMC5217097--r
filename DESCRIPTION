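Package: wcomp
Title: Weighted Composite Endpoints with Cone-Constrained Simultaneous Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted analysis of composite endpoints in two-arm randomized
    trials. Implements the weighted absolute-risk-difference statistic for
    binary and time-to-event composite endpoints, event-type schemes
    (exhaustive, competing risks, worst event, marginal), multinomial and
    Aalen-Johansen estimation of event-type probabilities with Greenwood-type
    and jackknife covariances, and simultaneous confidence intervals and
    tests that are valid across every weight vector in a user-specified
    convex cone via the chi-bar-squared distribution. Includes a
    constant-hazard multistate simulator with analytic probability oracles,
    simulation-based coverage studies, and power/sample-size calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    mvtnorm,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mstate,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
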