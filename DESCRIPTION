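Package: kinflow
Title: State-Space Kinetic Ising Models and Time-Varying Entropy Flow for
    Neural Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits kinetic Ising models with time-varying fields and causal
    couplings to binarized neural population activity using sequential
    Bayesian (Laplace) filtering and fixed-interval smoothing, with
    EM-optimized state-noise hyperparameters. Provides exact, sampling-based
    and dynamic mean-field estimators of time-varying entropy flow and
    entropy production, Gaussian-process simulators of nonstationary
    ground-truth parameters, trial-shuffling surrogates, an
    alternating-shrinking higher-order interaction model with a Gibbs
    sampler for misspecification studies, and downstream summary analyses
    (sparsity, coupling asymmetry, parameter-rescaling perturbation scans,
    behavioral sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
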