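Package: mangrovewave
Title: Probabilistic Wave Attenuation by Mangrove Greenbelts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale probabilistic assessment of wind- and swell-wave
    attenuation by mangrove greenbelts and their fronting tidal flats.
    Generates synthetic multivariate coastal forcing (extreme water levels,
    wave heights, peak periods, foreshore depths and belt widths) with
    percentile-anchored marginals and a Gaussian copula, selects
    representative conditions with a Maximum Dissimilarity Algorithm, runs a
    stationary one-dimensional bulk wave-energy-balance solver with
    depth-induced breaking, Collins bottom friction and multi-layer
    vegetation dissipation over schematized coast-normal transects, and
    summarizes the ensemble into attenuation-versus-forest-width percentile
    bands, uncertainty classes and foreshore/forest dissipation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
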