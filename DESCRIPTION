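Package: rwmscale
Title: Optimal Scaling and Preconditioning for Random Walk Metropolis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Large-sample (Bernstein-von Mises) tuning theory for random walk
    Metropolis algorithms. Evaluates the expected squared jumping distance
    (ESJD) and expected acceptance probability of the limiting chain by
    quadrature or Monte Carlo, performs dimension-dependent grid optimisation
    of the step-size parameter, builds Fisher-information-preconditioned
    proposal scalings, runs seeded random walk Metropolis chains with
    acceptance, ESJD and effective-sample-size diagnostics, and ships two
    worked studies: a Gaussian target with autoregressive correlation and a
    Bayesian logistic regression on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
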