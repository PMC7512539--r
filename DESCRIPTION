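Package: hellbayes
Title: Robust Bayesian Inference via Minimum Hellinger Distance and
    Nonparametric Density Posteriors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust and efficient parameter estimation for parametric
    families by combining the minimum Hellinger distance functional with
    Bayesian nonparametric density estimation.  Provides the MHB point
    estimator (minimum Hellinger distance to the expected posterior
    density), the BMH posterior (the nonparametric posterior over
    densities pushed through the minimum-Hellinger functional), a random
    histogram prior with Dirichlet weights on the unit interval, a
    conjugate Dirichlet-process mixture-of-normals Gibbs sampler for
    univariate and bivariate data, efficient-influence-function and
    Bernstein-von-Mises diagnostics, and gross-error contamination
    models for studying outlier rejection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
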