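Package: intensitybounds
Title: Intensity Bounds for the Delineation of Spatial Disease Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric uncertainty bounds for the delineation of spatial
    disease clusters on aggregated-area maps. Implements the circular Poisson
    spatial scan statistic with Monte Carlo significance testing, multinomial
    replication of the observed case map with per-replicate most-likely-cluster
    detection, the ranked log-likelihood-ratio intensity function and per-area
    quantile q measuring the plausibility of each area belonging to the real
    cluster, global and local (first-order-neighbourhood) Marshall
    empirical-Bayes rate smoothing as an alternative replication mean model,
    and a hexagonal-lattice benchmark generator with injected circular,
    L-shaped and double circular clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deldir,
    optparse
Config/testthat/edition: 3
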