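Package: growthsde
Title: Drift-and-Diffusion Models for Childhood Growth Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic differential equation (SDE) models for longitudinal
    child anthropometry, built around the linear-drift family
    dX = (p(t) + a1*X) dt + s*dW with polynomial p(t), whose transition
    ("slice") densities are Gaussian in closed form. Provides exact and
    Euler-Maruyama simulation, a synthetic-cohort generator emulating
    birth-cohort visit schedules, transition-likelihood maximum-likelihood
    estimation, mixed-effects fitting with child-level random effects via
    adaptive Gauss-Hermite quadrature, linear mixed-model baselines with
    AR(1) within-child errors, AIC/BIC model search with p-value trimming,
    and grid-based prediction of future weight-for-length z-score
    trajectories with likelihood-based locality and 10-fold sensitivity
    sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
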