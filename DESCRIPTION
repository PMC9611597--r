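Package: starmnl
Title: Bayesian Multinomial Structured Geo-Additive Regression for
    Clustered Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying geographic structure in categorical survey
    outcomes. Implements k-modes classification of nominal response vectors
    with user-primed initial modes, PSU-level category-proportion summaries
    with tri-colour blending and Moran's I spatial autocorrelation, and a
    fully Bayesian multinomial-logit structured additive regression (STAR)
    model combining fixed sociodemographic effects, a P-spline age smooth
    with second-order random-walk prior, iid primary-sampling-unit random
    effects and an intrinsic Markov-random-field region effect. Estimation
    is by Gibbs sampling with Polya-Gamma augmentation; model comparison by
    the deviance information criterion; convergence assessment by Geweke
    and Gelman-Rubin diagnostics. A synthetic-data generator emulates the
    hierarchical two-stage survey design (respondents within PSUs within
    regions, jittered coordinates) so every stage is testable without
    restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    splines,
    utils,
    grDevices,
    graphics,
    jsonlite,
    geosphere
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
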