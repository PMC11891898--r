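# Physical constants and static chemistry tables used across the package.
# All lengths are in nm, areas in nm^2, diffusion coefficients in
# 1e-5 cm^2 s^-1, viscosities in mPa s, temperatures in K.

#' Physical constants
#'
#' CODATA Boltzmann constant and the unit-conversion factors tying the
#' package's working units together (nm, mPa s, 1e-5 cm^2 s^-1).
#'
#' @format Named list with elements `k_B` (J K^-1), `D_unit` (m^2 s^-1 per
#'   diffusion unit), `eta_unit` (Pa s per mPa s), `length_unit` (m per nm).
#' @export
ride_constants <- list(
  k_B = 1.380649e-23,   # J/K, exact (2019 SI)
  D_unit = 1e-9,        # 1e-5 cm^2/s expressed in m^2/s
  eta_unit = 1e-3,      # mPa s in Pa s
  length_unit = 1e-9    # nm in m
)

#' Ewald self term for a simple cubic lattice
#'
#' Reference value of the unitless cubic-lattice self-interaction constant
#' appearing in hydrodynamic finite-size corrections under periodic boundary
#' conditions. [compute_xi_ew()] recomputes it from scratch; this constant is
#' the cached fallback.
#'
#' @export
XI_EW <- 2.837298

# 3-letter <-> 1-letter codes for the 20 standard amino acids
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- stats::setNames(AA3, AA1)

# Cap group residue names recognized as ACE / N-methylamide caps
CAP_RESIDUES <- c("ACE", "NME", "NMA")

# Average residue masses (g/mol) of amino acid residues in a chain
# (monomer mass minus one water), plus cap-group and water masses.
RESIDUE_MASS <- c(
  ALA = 71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY = 57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO = 97.1167, SER = 87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL = 99.1326,
  ACE = 43.0446,  # CH3-CO-
  NME = 30.0493,  # -NH-CH3
  NMA = 30.0493
)
WATER_MASS <- 18.0153

#' Default van der Waals radius set
#'
#' Bondi-style explicit-atom van der Waals radii in nm, used when assigning
#' radii for SESA computation. The radius file actually used alongside the
#' original MSMS-derived coefficients is not recorded anywhere public, so the
#' set shipped here is the standard Bondi table; every hydrodiffusivity scale
#' written by this package records the radius-set name it was derived with.
#'
#' @param name Identifier recorded in outputs. Only `"bondi"` is shipped.
#' @return A `ride_radius_set` object: list with `name`, `by_element`
#'   (named numeric, nm) and `by_atom_name` (named numeric overrides, nm).
#' @export
default_radius_set <- function(name = "bondi") {
  if (!identical(name, "bondi")) {
    stop("unknown radius set: ", name)
  }
  rs <- list(
    name = "bondi",
    by_element = c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                   S = 0.180, P = 0.180, F = 0.147, CL = 0.175,
                   BR = 0.185, I = 0.198, SE = 0.190),
    by_atom_name = numeric(0)
  )
  class(rs) <- "ride_radius_set"
  rs
}
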