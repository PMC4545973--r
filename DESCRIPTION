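Package: pope
Title: Post-Optimization Posterior Evaluation for Likelihood-Free Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian analysis of simulator-based (likelihood-free) models
    around an optimization problem: one-sided constraint kernels turn
    objective thresholds and output constraints into approximate Bayesian
    computation (ABC) likelihoods, sampled with marginal or pseudo-marginal
    Metropolis-Hastings. Includes online adaptation of kernel widths and
    objective thresholds, a synthetic-likelihood (conditional Gaussian)
    estimator with analytic CDFs, posterior and posterior-predictive
    summaries, analytic testbeds with quadrature oracles, and two
    biological demonstration simulators: a stochastic stem-cell niche
    geometry model and a deterministic one-dimensional Gierer-Meinhardt
    activator-inhibitor model of tumor spotting patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
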