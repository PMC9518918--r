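Package: snakeburden
Title: Decision-Analytic Estimation of the Economic and Disease Burden of
    Snakebite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Configuration-driven cohort decision-tree model for national and
    regional snakebite burden estimation. Computes expected victim counts by
    treatment-seeking path, antivenom indication and outcome; societal
    perspective costs (bottom-up direct medical, direct non-medical, and
    human-capital productivity losses with discounting and GDP-growth
    adjustment); disability-adjusted life years (YLL plus YLD) from a standard
    life table and disability weights; Monte Carlo probabilistic sensitivity
    analysis with percentile credible intervals; one-way (tornado) sensitivity
    analysis; and a post-traumatic stress disorder scenario. Ships a synthetic
    country-parameter generator for reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
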