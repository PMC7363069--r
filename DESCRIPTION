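Package: colorgame
Title: Emergent Color Naming via Reinforcement-Learning Signaling Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-agent color-naming game in which a sender and a
    receiver, modeled as small multilayer perceptrons, learn to communicate
    color chips over noisy channels using the REINFORCE policy gradient.
    Includes readers for World Color Survey style chip charts and naming
    files, a synthetic chart and planted-language generator, efficiency
    measures for color-naming systems (expected surprise, exemplar-based KL
    communication cost, correlation-clustering well-formedness), a
    maximizing-agreements correlation-clustering solver with an exact
    small-instance oracle, consensus maps, adjusted Rand comparisons, and
    experiment drivers for noise sweeps and term-count analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
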