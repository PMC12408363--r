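Package: blockprior
Title: Behavioural Modelling and Neural Decoding of Subjective Priors in
    Biased-Block Decision Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how rodents estimate and use a block-structured
    stimulus prior in two-alternative visual decision tasks, and how that
    subjective prior is represented in neural activity. Implements the task
    generative model (truncated-exponential block lengths, biased stimulus
    sides), a Bayes-optimal ideal observer and exponential action/stimulus
    history kernels, adaptive Metropolis-Hastings fitting with random-effects
    Bayesian model selection, nested cross-validated L1/L2 neural decoders with
    pseudosession null distributions, prior-conditioned neurometric curves,
    spectral Granger causality between bin-wise decoded priors, stepwise
    history orthogonalization, and maximum-likelihood neural decay-rate
    estimation. A synthetic-data module generates spike-count, widefield and
    behavioural-covariate data with controllable prior coupling, slow drift
    and directed coupling so every analysis can be exercised closed-loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
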