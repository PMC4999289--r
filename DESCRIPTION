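Package: nmareg
Title: Bayesian Network Meta-Analysis and Meta-Regression for Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Random-effects network meta-analysis of arm-level binary outcome
    data with a binomial likelihood and logit link, fitted by adaptive
    Markov chain Monte Carlo. Supports study-level covariate meta-regression
    with a common treatment-by-covariate interaction against the reference
    treatment, baseline-risk meta-regression using the latent trial baseline
    as covariate, residual-deviance/DIC/leverage model criticism,
    Brooks-Gelman-Rubin convergence diagnostics, a synthetic-network
    generator with known truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
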