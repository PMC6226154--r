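Package: zimap
Title: Spatial Zero-Inflated Count Models for Disease Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical and spatial zero-inflated Poisson and negative
    binomial models for mapping rare-event rates on areal (lattice) data,
    motivated by facility-based maternal mortality surveillance. Provides
    bivariate-normal district intercepts, intrinsic and proper conditional
    autoregressive (CAR) spatial priors including a bivariate intrinsic CAR
    linking the zero and count components, Metropolis-within-Gibbs posterior
    sampling, DIC and Brier-score model comparison via posterior predictive
    ordinates, Moran's I autocorrelation testing, district-level rate
    aggregation, and a fully seeded synthetic survey generator for
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    coda,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    ape,
    MASS
Config/testthat/edition: 3
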