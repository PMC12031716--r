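Package: tmazelearn
Title: Stochastic Linear-Operator Model of T-Maze Discrimination Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the Bush-Mosteller/Wyckoff style stochastic model of
    rat two-choice discrimination learning in a T-maze. Implements the
    eight-event trial probability tree, the eight linear learning operators
    acting on the attention probability, closed-form contraction constants
    (K1*-K4*) that diagnose solvability of the model's functional equation,
    a Picard fixed-point solver for the asymptotic choice-probability
    function on a grid over [0,1], and a seedable Monte Carlo simulator of
    trial-by-trial dynamics with fixed-point-versus-Monte-Carlo comparison
    utilities. A command-line interface exposes diagnostics, solving,
    simulation and comparison runs driven by a YAML/JSON configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
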