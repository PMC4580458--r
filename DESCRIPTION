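Package: smilegames
Title: Inverse Optimal Control Analysis of Dyadic Smile Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether two interacting partners time their
    smiles in a goal-directed way. Fits discrete-time hazard ("plant") models
    of a partner's smile onsets and offsets, solves for optimal smile-timing
    policies under candidate dyadic goals by value iteration, infers each
    agent's most probable goal from observed behaviour with a Boltzmann
    noisy-rationality likelihood, simulates controller-versus-adult smile
    sessions, and provides the accompanying statistical summaries (exact
    binomial tails, repeated-measures ANOVA with Greenhouse-Geisser
    correction, paired t-tests, Pearson correlation). Includes a synthetic
    dyad generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
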