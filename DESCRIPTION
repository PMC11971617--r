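Package: cgpcm
Title: Convexity-Constrained Random Effects Generalized Partial Credit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Latent-distribution-free marginal maximum likelihood estimation of
    the random effects generalized partial credit model for polytomously scored
    items.  The marginal distribution of observed score patterns is written in
    closed form through a truncated conditional cumulant-generating function of
    the latent trait, kept convex by a sum-of-squares parameterization of its
    second derivative, so estimation never requires a parametric assumption on
    the latent density or numerical integration.  Includes expected a
    posteriori (EAP) person scoring via conditional cumulants, estimation of
    latent population moments and cumulants, delta-method standard errors for
    transformed item parameters, a split-sample likelihood-ratio goodness-of-fit
    test, a convexity-constrained nominal response generalization, and
    simulation of polytomous response data under pluggable latent densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
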