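Package: eldergame
Title: Differential-Game Comparison of Elderly Medical-Care Modes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infinite-horizon discounted differential game between an elderly
    population and a government choosing among three epidemic-era medical
    service modes: no special care, home medical care, and a hospital "green
    channel". Provides closed-form feedback Nash equilibrium controls and
    affine value functions, independent numeric verification against the
    Hamilton-Jacobi-Bellman equations, state trajectories and discounted
    welfare integrals, affine-in-inverse-cost value decompositions,
    crossover-cost thresholds, sensitivity sweeps, and a seeded generator of
    admissible parameter scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
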