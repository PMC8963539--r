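Package: beliefcov
Title: Task-Induced Neural Covariability from Bayesian Learning and Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how Bayesian
    learning and inference shape correlated variability in sensory neural
    populations. Implements discretized-grid Bayesian observers with
    self-consistent task priors learned by gradient descent on a
    Kullback-Leibler objective, trial-to-trial covariance of posterior
    densities and its prior-filtering approximation, distributional codes
    mapping posteriors to spike counts (including the Linear Distributional
    Code mixture test), decision-related statistics (choice-triggered
    averages, choice probabilities, d-prime, covariance decompositions into
    intrinsic and belief-driven components), and a sampling-based
    sparse-coding V1 model whose noise-correlation eigenstructure reveals
    internal task beliefs under cued task switching.
License: MIT
Encoding: UTF-8
Imports: Rcpp, stats, graphics, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
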