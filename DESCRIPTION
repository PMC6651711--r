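Package: memperm
Title: Membrane Mechanics and Water Permeability from Simulation Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimators for the structural, mechanical and permeation analysis
    of bilayer membranes from molecular-simulation ensembles: deuterium order
    parameters and gauche-conformer fractions of alkyl chains, cavity-density
    depth profiles, fluctuation-based area compressibility, molecular tilt and
    bending moduli (height-fluctuation spectrum), Helfrich bending-energy
    profiles, and water permeability via the inhomogeneous
    solubility-diffusivity model (thermodynamic integration of constraint
    forces and force-autocorrelation local diffusivities). Includes a
    synthetic-membrane generator with analytically known ground truth so every
    estimator ships with a parameter-recovery test, plus readers and writers
    for GRO/PDB structures, plain-text trajectories and XVG/CSV time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    jsonlite,
    minpack.lm,
    pracma,
    bio3d,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
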