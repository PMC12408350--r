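Package: spikedrift
Title: Latent Langevin Dynamics and Neuronal Tuning Inferred from Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint nonparametric inference of one-dimensional latent Langevin
    dynamics (potential landscape, noise magnitude, initial-state density) and
    single-neuron tuning functions from trial-structured spike trains in
    reaction-time tasks. Trials end when the latent state first reaches a
    domain boundary, so the likelihood is built from a modified Fokker-Planck
    propagator with absorbing boundaries and spike-emission decay. Includes a
    functional ADAM optimizer with mini-batching and scalar line searches,
    feature-consistency model selection via trajectory entropy and
    Jensen-Shannon divergence between data splits, bootstrap uncertainty
    bands, continuous-state Viterbi decoding, spike-time R-squared by time
    rescaling, renewal-based point-process variability estimation, choice
    prediction with balanced accuracy, and synthetic-data generators
    (Langevin-Poisson trials, a two-pool mean-field attractor network, and a
    rank-two distributed recurrent network).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    glmnet,
    deSolve,
    pracma,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
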