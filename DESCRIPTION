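Package: dtprec
Title: Case-Based and Neural Recommenders for Diagnostic-Treatment Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a patient's hospital trajectory as a discrete controlled
    process with memory: a sequence of state vectors holding cumulative
    (integral) control quantities such as full drug doses alongside monitored
    clinical properties. On banks of such trajectories it trains and compares
    three next-step recommendation engines: a case-based small-world state
    graph searched by random-restart greedy descent, a single-layer network
    with Gaussian bell activation trained by explicit-gradient steepest
    descent, and a probabilistic neural network (Parzen kernel Bayes
    classifier) with sigma-scaled diagonal-covariance Gaussian kernels.
    Includes a seeded protocol-driven synthetic trajectory generator,
    confusion-matrix and ROC evaluation, and a JSON Lines bank format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
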