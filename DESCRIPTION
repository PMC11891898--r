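Package: ride
Title: Residue Interaction Diffusion Estimation for Peptides and Proteins
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts infinitely dilute translational diffusion coefficients
    of peptides and proteins by additive assembly of a hydrodynamic radius
    from per-residue hydrodiffusivity coefficients weighted by
    solvent-excluded surface area (SESA), following the Stokes-Einstein
    relation. Includes a numerical SESA engine based on the rolling-probe
    surface definition, readers for PDB structures and MSMS-style per-atom
    area files, ideal-geometry peptide builders, mean-square-displacement
    analysis of Brownian trajectories, finite-size extrapolation of apparent
    diffusion coefficients under cubic periodic boundary conditions
    (including the Ewald simple-cubic lattice self term), water viscosity
    models with temperature and NaCl concentration dependence, a
    periodic-perturbation viscosity estimator, and a Polson-style
    mass-relation baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
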