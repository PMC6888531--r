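Package: sorbkit
Title: Equilibrium Adsorption Isotherm Modeling for Batch Enrichment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing batch equilibrium adsorption data from
    solute-enrichment experiments. Implements six classical isotherm
    families (Langmuir, Freundlich, Redlich-Peterson, Temkin,
    Dubinin-Radushkevich, Dubinin-Astakhov) with both linearized
    least-squares estimation (including the embedded one-dimensional
    r-squared-maximizing search required by the three-parameter models)
    and direct nonlinear estimation by minimization of Marquardt's
    percent standard deviation (MPSD). Provides derived physico-chemical
    metrics (mean free energy of adsorption from Polanyi-potential
    models, molar uptake ratios, surface-normalized capacities), model
    ranking, a mass-balance simulator for batch experiments with seeded
    measurement noise, CSV input/output, and report generation. Ships
    reference parameter tables for 18beta-glycyrrhetinic acid adsorption
    on amine-functionalized mesoporous (SBA-15) and non-porous (Aerosil)
    silicas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
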