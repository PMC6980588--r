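Package: warsawlh
Title: Life-History Analysis of Northern Gulf of Mexico Warsaw Grouper
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the life-history analysis of a long-lived, data-poor
    deepwater grouper: bomb-radiocarbon validation of otolith age estimates
    against a loess-fitted coral and known-age otolith reference series,
    reader-precision statistics (average percent error, coefficient of
    variation, percent agreement), depth regression of dissolved inorganic
    carbon radiocarbon for juvenile-habitat inference, and Bayesian
    estimation of von Bertalanffy growth, logistic gear selectivity, and
    natural and fishing mortality from length-age composition data using an
    equilibrium growth-type-group catch-composition model fit by adaptive
    Metropolis-Hastings. Synthetic-data generators emulate every input so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    coda,
    car,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
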