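Package: zdilution
Title: In Silico Dilution Experiments for Microzooplankton Grazing Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates classical and Z-dilution grazing-rate experiments for
    phytoplankton populations governed by exponential or logistic growth with
    microzooplankton grazing. Bottle dynamics are solved in closed form,
    apparent growth rates are regressed on the dilution fraction, and the
    resulting mortality estimates are compared against the true grazing rate
    to quantify the bias introduced by niche competition. Includes a sweep
    over grazing pressure, an estimator of the niche-competition loss rate
    from paired classical and Z-dilution experiments, ggplot2 visualisations,
    and a command-line interface with YAML configuration.
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
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
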