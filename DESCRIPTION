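Package: punisim
Title: Targeted Punishment Dynamics in Heterogeneous Social Dilemmas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator and analysis toolkit for binary-state
    cooperation dynamics in a population of heterogeneous players facing a
    social dilemma with punishment. Players cooperate or defect with a
    sigmoidal (Ising/Glauber-like) probability driven by an intrinsic
    predisposition plus a punishment term divided among the players
    currently deemed at fault. Implements the uniform, single-file and
    groups fault-assignment strategies, synchronous Monte-Carlo dynamics,
    stationary-density and time-to-cooperation estimation, phase-diagram
    parameter sweeps, the deterministic mean-field map with fixed-point and
    stability analysis, and an exact Markov-chain oracle for small
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
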