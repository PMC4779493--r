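Package: geeraerd
Title: Explicit Nonisothermal Solutions of the Geeraerd Microbial Survival Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of the original and modified Geeraerd
    shoulder/tail microbial inactivation models under nonisothermal (dynamic
    temperature) conditions. Survival curves are computed from a closed-form
    expression of the log survival ratio in which the time integral of the
    temperature-dependent specific inactivation rate (Bigelow secondary
    model) is accumulated over a discrete temperature profile by a
    per-interval Simpson rule. Includes an independent adaptive ODE oracle
    for validation, a time-step selection rule, simultaneous multi-dataset
    nonlinear least-squares parameter identification with shared and
    per-dataset parameters, a heating-rate adaptation factor for heat-stress
    hardening, and a synthetic-data generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
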