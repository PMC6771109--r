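Package: atlasmooth
Title: Bayesian Spatial Smoothing and Uncertainty Visualisation for
    Small-Area Cancer Atlases
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building small-area cancer atlases: binary
    first-order adjacency graphs with island repair, indirect age
    standardisation of incidence counts, period-method relative-survival
    tables, Bayesian disease mapping of standardised incidence ratios and
    excess hazard ratios with the Leroux conditional autoregressive prior
    fitted by Markov chain Monte Carlo, posterior uncertainty summaries
    (equal-tailed credible intervals, differences in posterior
    probabilities, Geweke convergence flags), Tango's maximised excess
    events test for overall spatial variation, and the uncertainty-aware
    visual encodings (log-linear diverging colour scale, transparency
    masks, V-plots, wave plots, regional summaries) used by modern
    interactive cancer atlases.  A synthetic-data generator with known
    ground truth stands in for restricted registry inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
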