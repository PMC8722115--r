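Package: plattrial
Title: Bayesian Platform Trial Design, Simulation and Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-evaluation engine for Bayesian phase II platform trials
    with a shared control arm, binary endpoints and staggered entry of
    experimental arms. Implements conjugate beta-binomial posterior updating
    and the posterior probability of superiority over a margin, adaptive
    randomization with a control-arm cap and 1/(1+3m) rescaling, Bayesian
    toxicity monitoring with exact operating characteristics, grid
    calibration of the decision threshold to a type-I-error target, exact
    Clopper-Pearson confidence intervals, and a Monte-Carlo simulator of the
    full multi-arm platform that reports per-arm operating characteristics
    (probability of claiming success, mean sample sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
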