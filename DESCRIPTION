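Package: optbound
Title: Reward-Rate Optimal Dynamic and Static Decision Bounds for Expanded
    Judgment Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives and evaluates reward-rate optimal decision criteria for
    two-alternative expanded judgment tasks in which two stimuli flash as
    independent Bernoulli processes and the observer must decide which
    flashes at the higher rate.  Provides Bayesian belief updating under
    exactly known stimulus rates and under beta-distributed rate
    uncertainty (beta-binomial marginal likelihoods), finite-horizon
    backward-induction dynamic programming for the optimal time-varying
    bound, extraction of criterion curves on the posterior-probability
    scale, exact forward-propagation and Monte Carlo policy evaluation
    with logistic sampling-cost schedules, best-static-threshold search,
    and deterministic parameter-space sweeps comparing static against
    dynamic bounds across task difficulty, cost direction, and prior
    precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
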