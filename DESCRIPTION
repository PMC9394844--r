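Package: kinarow
Title: Search, Scoring Strategies and Choice Models for k-in-a-Row End-Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying strategic search in "k-in-a-row" end-game puzzles:
    board representation with winning-path geometry, five heuristic scoring
    strategies (density, linear, non-linear, path interaction, forcing), a
    spatial "shutter" pruning heuristic, deterministic and stochastic
    alpha-beta tree search, Monte-Carlo tree search, maximum-likelihood
    fitting of lapse-rate choice models to move-by-move search trajectories
    with AIC model selection, entropy and missed-win analyses, and
    accuracy-versus-computation Pareto sweeps. Includes generators for
    verified forced-win boards and simulated participant cohorts so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
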