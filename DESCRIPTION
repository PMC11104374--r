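Package: advicehgf
Title: Hierarchical Gaussian Filter Models of Social Advice-Taking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial belief-updating models for a social learning task
    in which participants weigh a non-social cue against the advice of an
    adviser whose intentions change over time. Implements the binary 3-level
    Hierarchical Gaussian Filter and a mean-reverting variant with a drift at
    the volatility level, a volatility-gated response model, MAP estimation
    under empirical priors with Laplace-approximated log model evidence,
    random-effects Bayesian model selection with protected exceedance
    probabilities, model and parameter recovery suites, and synthetic task
    and cohort generators for end-to-end simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
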