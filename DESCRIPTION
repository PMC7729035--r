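Package: biofilmgame
Title: Minimal Population Dynamics and Evolutionary Games for Social
    Microbe Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing a minimal three-subpopulation model of a
    social microbe community (resistant, producer and motile cells) driven
    by the cost of public-goods production under antibiotic stress.
    Provides the ordinary differential equation system with closed-form
    steady states, Jacobian, characteristic polynomial and Hopf
    bifurcation condition; stiffness-aware time-course simulation of the
    resistant-cell fraction R/(R+P); classification of trajectories into
    spike-like, sinusoidal, damped and monotonic dynamic regimes;
    amplitude-envelope bifurcation scans over the public-goods cost; and
    the companion evolutionary-game analyses: the cyclic three-strategy
    (rock-paper-scissors) game, stress-conditioned two-strategy bimatrix
    games, pure and mixed Nash equilibrium enumeration with a zero-sum
    minimax cross-check, and single-population replicator dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    boot,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
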