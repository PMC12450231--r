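Package: coopclim
Title: Evolutionary Agent-Based Simulation of Cooperation Under Climate Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evolutionary agent-based simulator of hominin cooperation under
    Pleistocene climate constraints in a two-region mountain-corridor
    landscape. Implements conformist-transmission and payoff-biased strategy
    dynamics with punishment, seasonal climate scenario forcing, an
    energy/body-temperature survival physiology, resource foraging on a patch
    grid, shelter ("attractor") founding and collapse, threshold-driven
    migration, and a factorial experiment driver with repetition bands.
    Results are returned as tidy tibbles with broom-style tidy() and glance()
    methods and ggplot2 autoplot() figures.
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
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
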