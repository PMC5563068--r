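Package: betamix
Title: Beta Mixture Models via an Iterated Method of Moments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits mixtures of beta distributions to data on the unit
    interval, including observations exactly at 0 and 1, by alternating
    an EM-style responsibility (E-) step with per-component method of
    moments re-estimation instead of maximum likelihood.  Includes
    Kolmogorov-Smirnov based selection of the number of components,
    rules for classifying DNA methylation levels into methylation
    states (unmethylated, semi-methylated, fully methylated), and
    simulation drivers that benchmark adaptive mixture-based
    classification against fixed thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
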