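Package: scavsim
Title: Trophic-Web Simulation of European Facultative Scavengers Under
    Hunting and Wolf Presence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a five-state trophic web (vegetation, deer, wild
    boar, facultative scavengers, wolf) with human hunting and explicit
    carrion-flux bookkeeping, using a Lotka-Volterra style ordinary
    differential equation model with Holling type-II functional
    responses.  Provides scenario grids over boar/wolf presence and
    hunting regimes, factorial parameter sensitivity sweeps, multistart
    equilibrium checks, derived summary series (scavenger growth
    sources, carrion origin decomposition), tidy tabular outputs,
    ggplot2 figures, and a command-line entry point for reproducible
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
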