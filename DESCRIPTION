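Package: orivar
Title: Orientation-Variance Tuning, Archetype Clustering and Recurrent
    Ring-Network Modelling of V1 Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how primary visual cortex responses degrade
    with the orientation variance of naturalistic band-pass noise stimuli
    ("Motion Clouds"). Provides stimulus synthesis with a parameterised
    orientation envelope, a generator of synthetic inhomogeneous-Poisson
    spike datasets with variance-vulnerable and variance-resilient response
    archetypes, single-neuron analysis (von Mises tuning fits, circular
    variance, Naka-Rushton variance-tuning functions, tuning significance,
    response dynamics), PCA + K-means archetype clustering with a continuous
    vulnerability score, sliding-window multinomial logistic population
    decoding of orientation and its variance, and a recurrent ring-network
    model with excitatory/inhibitory von Mises connectivity that reproduces
    both archetypes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
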