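Package: chainrecip
Title: Simulation and Analysis of Chained Indirect-Reciprocity Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing chained gift-giving
    (indirect reciprocity) experiments in which groups of participants
    make repeated binary cooperate/defect decisions along simultaneously
    running chains, under either a pay-it-forward (upstream) or a
    reputation-based (downstream) information protocol.  Provides
    constrained chain-schedule construction with no repeated
    donor-recipient pairs, a logistic behaviour model with
    per-participant random intercepts for generating synthetic decision
    logs, conditional and unconditional cooperation statistics and
    reciprocity scores, run-length extraction along chains with
    geometric null models fitted under i.i.d. and two-state Markov
    assumptions, Kolmogorov-Smirnov goodness-of-fit tests (asymptotic
    and Monte-Carlo), and between-game correlation analyses of
    per-participant cooperation probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
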