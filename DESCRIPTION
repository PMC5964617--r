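Package: mwablate
Title: Coupled Electromagnetic-Thermal Simulation of Microwave Breast Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric finite-element simulator for interstitial microwave
    ablation of breast tissue with a 2.45 GHz double short-distance slot coaxial
    antenna. Solves the frequency-domain electromagnetic problem (azimuthal
    magnetic field formulation with a coaxial TEM port), derives the volumetric
    SAR heat source, and feeds it into a steady or transient Pennes bioheat
    solve. Provides antenna design formulas, S11/SWR bookkeeping, sensor
    temperature traces, 60 degree Celsius isotherm lesion areas, scenario
    presets matching published power/time protocols, manufactured-solution
    verification fixtures, and synthetic experimental traces for
    model-versus-measurement comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
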