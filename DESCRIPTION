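Package: kerneltd
Title: Kernel Temporal-Difference Learning for Policy Evaluation and
    Neural Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online reinforcement learning with kernel temporal differences,
    KTD(lambda), in a reproducing kernel Hilbert space.  Implements policy
    evaluation on 13-state absorbing Markov reward chains (linear and
    nonlinear value benchmarks) with exact matrix-inversion solutions and
    expected-update convergence diagnostics, Q-learning via kernel temporal
    differences with epsilon-greedy exploration and eligibility traces,
    online dictionary sparsification (quantization and kernel-distance
    criteria), linear TD(lambda) and Monte-Carlo Gaussian-process TD
    baselines, an automatic kernel-bandwidth heuristic, and a synthetic
    center-out reaching environment with a class-structured neural-state
    generator for brain-machine-interface style decoding experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
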