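Package: thermoflux
Title: Probabilistic Thermodynamic Analysis of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint probabilistic modeling of metabolite concentrations and
    Gibbs reaction energies under steady-state flux constraints for
    constraint-based metabolic models. Provides probabilistic metabolic
    optimization (PMO) to locate the most probable thermodynamic state,
    structural consistency checking via internal elementary flux modes and
    forced-cycle detection, Hit-and-Run Markov chain Monte Carlo sampling of
    the non-convex steady-state thermodynamic space, thermodynamics-weighted
    flux sampling with Coordinate Hit-and-Run with Rounding, and convergence
    and distribution-comparison diagnostics. Reads COBRA-style JSON and SBML
    (level 3, fbc) models; ships a synthetic fixture generator so every stage
    can be exercised on small networks.
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
    graphics,
    jsonlite,
    purrr,
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
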