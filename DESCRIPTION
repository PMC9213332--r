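Package: adaptdyn
Title: Evolutionary Dynamics of Adaptation to DNA Damage in Trait-Structured Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a cooperative two-population
    non-local reaction-diffusion model of evolutionary adaptation to DNA damage.
    Healthy and checkpoint-adapted cell densities are structured by a heritable
    trait (mean adaptation timing, or heterogeneity of the adaptation time) and
    coupled through conversion terms derived from a quasi-static description of
    the damaged compartment. The package builds the effective growth and
    conversion coefficients from biological repair/adaptation/death rates by
    quadrature of the damaged-cell survival kernel, integrates the rare-mutation
    (small-epsilon) scaled system with a Crank-Nicolson scheme under Neumann
    boundary conditions, computes the Hamiltonian (effective) fitness and the
    associated spectral quantities that predict the selected trait, solves the
    stationary ground-state eigenproblem for the summed population, and provides
    diagnostics (Hopf-Cole fields, population-ratio convergence, total-mass
    bounds, Dirac-concentration metrics) together with preset numerical
    experiments in constant and periodically varying environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
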