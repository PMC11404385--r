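Package: glmpo2pls
Title: One-Stage Joint Modelling of Two Omics Matrices and an Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Probabilistic two-way orthogonal partial least squares with an
    outcome variable (GLM-PO2PLS). Decomposes two omics matrices into joint,
    data-specific and residual parts and links a continuous or binary outcome
    to the joint latent components through a generalized linear model.
    Maximum-likelihood estimation by EM (exact conditional moments for a
    Gaussian outcome; Gauss-Hermite quadrature and a backtracking gradient
    M-step for a Bernoulli outcome), chi-square Wald tests of the
    omics-outcome association based on the Louis observed information, a
    model-faithful simulator, scree utilities for choosing the numbers of
    components, and a simulation-study harness with ridge baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, pracma, glmnet
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
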