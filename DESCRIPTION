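Package: poretrace
Title: Pore-Opening Dynamics of Single Vesicles from Amperometric Spikes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and inverse reconstruction of membrane
    pore-opening dynamics during vesicle impact electrochemical cytometry
    (VIEC). Solves the axisymmetric diffusion problem for vesicular
    catecholamine release through a dynamically expanding electroporation
    pore onto an absorbing microdisk electrode, reconstructs the
    pore-radius trajectory R_p(t) from a measured current spike by
    sequential one-dimensional Nelder-Mead fitting, and provides spike
    feature extraction (charge, rise time, exponential-decay
    classification), population-level scaling analyses of pore size
    versus vesicle size, and a synthetic-data generator for closed-loop
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    withr,
    yaml
Config/testthat/edition: 3
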