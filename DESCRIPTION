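Package: glcdesign
Title: Systematic Design of Genetic Lysis Circuits for Cell Population Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic models and design tools for synthetic genetic lysis
    circuits that hold an Escherichia coli population at a prescribed density.
    Provides Hill-function models of repressor- and activator-regulated
    promoter-RBS components coupled to logistic cell growth, deterministic and
    stochastic (Euler-Maruyama) time-domain simulation, closed-form steady-state
    models with Monte-Carlo parameter perturbation, synthetic promoter-RBS
    component libraries with characterization fitting, and a genetic-algorithm
    search (with an exhaustive-search oracle) that selects a promoter-RBS
    component pair and a feasible inducer range so the steady-state density
    tracks a user-prescribed input/output response.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
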