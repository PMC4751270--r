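Package: trustgames
Title: Trust-Dynamics Cognitive Model for Iterated Games of Strategic
    Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a learning agent whose choices in iterated
    Prisoner's Dilemma and Chicken Game are driven by instance-based
    sequence prediction, utility learning, and a two-accumulator trust
    mechanism (trust and trust-invest) that switches among three reward
    functions.  Includes the scripted Tit-for-Tat, Pavlov, and
    Pavlov-Tit-for-Tat confederate agents with trustworthiness
    manipulations, a 16-condition simulation experiment with persistent
    model state across two 50-round games, fixed-reward and
    reactive-trust model variants for comparison, and an analysis layer
    computing round-by-round outcome proportions, repetition
    propensities, correlation/RMSD fit statistics, paired transfer
    tests, and Steiger's Z for dependent correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
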