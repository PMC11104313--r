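Package: competingcritics
Title: Competing Optimistic and Pessimistic Critics for Human Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for a dual-critic model of human reward
    learning and choice. Two risk-sensitive temporal-difference critics -- an
    optimistic value function that up-weights positive prediction errors and a
    pessimistic one that up-weights negative prediction errors -- are learned
    from the same experience, and the interval they span drives choice through
    a uniform utility draw combined with epsilon-greedy selection. Includes a
    four-moment (mean, standard deviation, skewness, kurtosis) reward
    generator built on the Pearson system, four task environments (single-arm
    reward learning, the Iowa Gambling Task, the two-stage Markov task, and a
    stock-market betting task), a seeded vectorized replicate engine with
    (k+, k-) grid sweeps, and readouts for value-function geometry, deck
    preference, stay probabilities, reaction-time proxies, and
    dopamine/serotonin-like update transients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
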