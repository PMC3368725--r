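Package: sacr
Title: Stochastic Kinetics of the Spindle Assembly Checkpoint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Markovian analysis of Cdc20 inhibition and APC/C activation at
    the spindle assembly checkpoint (SAC). Provides the closed-form
    probability that no APC/C activation occurs during the checkpoint, the
    binomial equilibrium distribution of free Cdc20, the mean first-passage
    time to full APC/C activation at anaphase onset (occupation-time solve
    of the two-dimensional production/binding chain), and a constraint-domain
    scan over the production rate lambda*S and inhibition rate k-1. Includes
    a stiff chemical-master-equation integrator and an exact Gillespie
    simulator as independent numerical oracles. Results are tibbles with
    broom-style tidy()/glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
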