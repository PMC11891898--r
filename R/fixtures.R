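# fixtures: deterministic generators of test inputs -- ideal peptide
# conformers built from internal coordinates, sphere clusters with known
# areas, Brownian trajectories with known D, and finite-size series.

deg <- function(x) x * pi / 180

# Natural-extension-reference-frame placement: position d bonded to c with
# |d-c| = bond, angle(d,c,b) = angle and torsion(d,c,b,a) = torsion.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg(angle); tor <- deg(torsion)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("colinear reference atoms in internal-coordinate build")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal backbone geometry (nm / degrees), standard peptide values.
BB <- list(
  b_N_CA = 0.1458, b_CA_C = 0.1525, b_C_N = 0.1329, b_C_O = 0.1231,
  b_C_OX = 0.1249, b_ACE_CH3 = 0.1507, b_NME_CH3 = 0.1449,
  a_C_N_CA = 121.7, a_N_CA_C = 111.2, a_CA_C_N = 116.2,
  a_CA_C_O = 120.8, a_CH3_C_N = 116.6, a_O_C_N = 122.9,
  a_C_N_CH3 = 121.7, a_O_C_OX = 117.0
)

# Side-chain internal-coordinate templates: one row per heavy atom beyond CB,
# referencing previously placed atoms of the same residue. A single canonical
# rotamer (mostly all-trans chi angles) is used throughout; side-chain
# conformation is not varied.
sc_row <- function(name, p, aref, tref, b, a, t) {
  data.frame(name = name, p = p, aref = aref, tref = tref,
             b = b, a = a, t = t, stringsAsFactors = FALSE)
}

SIDE_CHAINS <- list(
  GLY = NULL,
  ALA = NULL,
  SER = sc_row("OG", "CB", "CA", "N", 0.1417, 110.8, 180),
  CYS = sc_row("SG", "CB", "CA", "N", 0.1808, 113.8, 180),
  THR = rbind(sc_row("OG1", "CB", "CA", "N", 0.1433, 109.6, 180),
              sc_row("CG2", "CB", "CA", "OG1", 0.1521, 110.5, -120)),
  VAL = rbind(sc_row("CG1", "CB", "CA", "N", 0.1527, 110.5, 180),
              sc_row("CG2", "CB", "CA", "CG1", 0.1527, 110.5, 120)),
  ILE = rbind(sc_row("CG1", "CB", "CA", "N", 0.1530, 110.4, 180),
              sc_row("CG2", "CB", "CA", "CG1", 0.1521, 110.5, -120),
              sc_row("CD1", "CG1", "CB", "CA", 0.1513, 113.8, 180)),
  LEU = rbind(sc_row("CG", "CB", "CA", "N", 0.1530, 116.3, 180),
              sc_row("CD1", "CG", "CB", "CA", 0.1521, 110.7, 180),
              sc_row("CD2", "CG", "CB", "CD1", 0.1521, 110.7, 120)),
  MET = rbind(sc_row("CG", "CB", "CA", "N", 0.1520, 114.1, 180),
              sc_row("SD", "CG", "CB", "CA", 0.1807, 112.7, 180),
              sc_row("CE", "SD", "CG", "CB", 0.1789, 100.9, 180)),
  PRO = rbind(sc_row("CG", "CB", "CA", "N", 0.1495, 104.5, 30),
              sc_row("CD", "CG", "CB", "CA", 0.1507, 106.1, -35)),
  PHE = rbind(sc_row("CG", "CB", "CA", "N", 0.1505, 113.8, 180),
              sc_row("CD1", "CG", "CB", "CA", 0.1390, 120.7, 90),
              sc_row("CD2", "CG", "CB", "CD1", 0.1390, 120.7, 180),
              sc_row("CE1", "CD1", "CG", "CB", 0.1390, 120.7, 180),
              sc_row("CE2", "CD2", "CG", "CB", 0.1390, 120.7, 180),
              sc_row("CZ", "CE1", "CD1", "CG", 0.1390, 120.0, 0)),
  TYR = rbind(sc_row("CG", "CB", "CA", "N", 0.1505, 113.8, 180),
              sc_row("CD1", "CG", "CB", "CA", 0.1390, 120.7, 90),
              sc_row("CD2", "CG", "CB", "CD1", 0.1390, 120.7, 180),
              sc_row("CE1", "CD1", "CG", "CB", 0.1390, 120.7, 180),
              sc_row("CE2", "CD2", "CG", "CB", 0.1390, 120.7, 180),
              sc_row("CZ", "CE1", "CD1", "CG", 0.1390, 120.0, 0),
              sc_row("OH", "CZ", "CE1", "CD1", 0.1376, 119.9, 180)),
  TRP = rbind(sc_row("CG", "CB", "CA", "N", 0.1498, 113.6, 180),
              sc_row("CD1", "CG", "CB", "CA", 0.1365, 126.9, 90),
              sc_row("CD2", "CG", "CB", "CD1", 0.1433, 126.6, 180),
              sc_row("NE1", "CD1", "CG", "CD2", 0.1374, 110.2, 0),
              sc_row("CE2", "NE1", "CD1", "CG", 0.1370, 109.0, 0),
              sc_row("CE3", "CD2", "CG", "CD1", 0.1400, 133.9, 180),
              sc_row("CZ2", "CE2", "NE1", "CD1", 0.1394, 128.8, 180),
              sc_row("CZ3", "CE3", "CD2", "CG", 0.1391, 118.7, 180),
              sc_row("CH2", "CZ2", "CE2", "NE1", 0.1368, 116.1, 180)),
  HIS = rbind(sc_row("CG", "CB", "CA", "N", 0.1504, 113.8, 180),
              sc_row("ND1", "CG", "CB", "CA", 0.1378, 122.9, -90),
              sc_row("CD2", "CG", "CB", "ND1", 0.1356, 131.2, 180),
              sc_row("CE1", "ND1", "CG", "CD2", 0.1321, 109.3, 0),
              sc_row("NE2", "CD2", "CG", "ND1", 0.1374, 107.2, 0)),
  ASP = rbind(sc_row("CG", "CB", "CA", "N", 0.1516, 112.6, 180),
              sc_row("OD1", "CG", "CB", "CA", 0.1249, 118.4, 0),
              sc_row("OD2", "CG", "CB", "OD1", 0.1249, 118.4, 180)),
  ASN = rbind(sc_row("CG", "CB", "CA", "N", 0.1516, 112.6, 180),
              sc_row("OD1", "CG", "CB", "CA", 0.1231, 120.8, 0),
              sc_row("ND2", "CG", "CB", "OD1", 0.1328, 116.4, 180)),
  GLU = rbind(sc_row("CG", "CB", "CA", "N", 0.1520, 114.1, 180),
              sc_row("CD", "CG", "CB", "CA", 0.1516, 112.6, 180),
              sc_row("OE1", "CD", "CG", "CB", 0.1249, 118.4, 0),
              sc_row("OE2", "CD", "CG", "OE1", 0.1249, 118.4, 180)),
  GLN = rbind(sc_row("CG", "CB", "CA", "N", 0.1520, 114.1, 180),
              sc_row("CD", "CG", "CB", "CA", 0.1516, 112.6, 180),
              sc_row("OE1", "CD", "CG", "CB", 0.1231, 120.8, 0),
              sc_row("NE2", "CD", "CG", "OE1", 0.1328, 116.4, 180)),
  LYS = rbind(sc_row("CG", "CB", "CA", "N", 0.1520, 114.1, 180),
              sc_row("CD", "CG", "CB", "CA", 0.1520, 111.3, 180),
              sc_row("CE", "CD", "CG", "CB", 0.1520, 111.3, 180),
              sc_row("NZ", "CE", "CD", "CG", 0.1489, 111.9, 180)),
  ARG = rbind(sc_row("CG", "CB", "CA", "N", 0.1520, 114.1, 180),
              sc_row("CD", "CG", "CB", "CA", 0.1520, 111.3, 180),
              sc_row("NE", "CD", "CG", "CB", 0.1461, 112.0, 180),
              sc_row("CZ", "NE", "CD", "CG", 0.1329, 124.2, 180),
              sc_row("NH1", "CZ", "NE", "CD", 0.1326, 120.0, 0),
              sc_row("NH2", "CZ", "NE", "NH1", 0.1326, 120.0, 180))
)

# Backbone dihedrals per named conformation (phi, psi); omega is always 180.
CONFORMATIONS <- list(
  extended = c(phi = 180, psi = 180),
  alpha_helix = c(phi = -57, psi = -47),
  polyproline = c(phi = -75, psi = 145)
)

#' Build an ideal-geometry peptide structure
#'
#' Constructs a heavy-atom peptide from ideal internal coordinates (standard
#' bond lengths and angles, a single canonical side-chain rotamer) at a named
#' backbone conformation: `"extended"` (phi = psi = 180), `"alpha_helix"`
#' (phi = -57, psi = -47) or `"polyproline"` (phi = -75, psi = 145). With
#' `capped = TRUE` the backbone is terminated by ACE and NME groups; otherwise
#' the bare zwitterionic backbone is built (with a terminal OXT oxygen).
#' Construction is fully deterministic: identical specs yield bit-identical
#' coordinates.
#'
#' @param sequence 1-letter amino-acid string (standard residues only).
#' @param conformation One of `"extended"`, `"alpha_helix"`, `"polyproline"`.
#' @param capped Add ACE/NME caps (default `TRUE`).
#' @return A `ride_structure`.
#' @export
build_peptide <- function(sequence, conformation = "extended", capped = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(letters1 %in% AA1)) {
    stop("unknown residue letter(s): ",
         paste(setdiff(letters1, AA1), collapse = ", "))
  }
  if (!conformation %in% names(CONFORMATIONS)) {
    stop("unknown conformation: ", conformation)
  }
  res3 <- AA3_FROM_1[letters1]
  n_res <- length(res3)
  dih <- CONFORMATIONS[[conformation]]
  phi <- dih[["phi"]]; psi <- dih[["psi"]]

  # ---- main chain -------------------------------------------------------
  # chain atom list: (ACE CH3, ACE C)? + (N, CA, C) per residue + (NME N, CH3)?
  # torsion sequence along the chain is ... omega, phi, psi, omega, phi, psi ...
  coords <- list()   # named "<resslot>|<atomname>" -> xyz
  put <- function(slot, name, xyz) coords[[paste0(slot, "|", name)]] <<- xyz
  get_xyz <- function(slot, name) coords[[paste0(slot, "|", name)]]

  chain <- list()  # each: slot, name, bond, angle, torsion (to previous three)
  add <- function(slot, name, bond, angle, torsion) {
    chain[[length(chain) + 1]] <<- list(slot = slot, name = name, bond = bond,
                                        angle = angle, torsion = torsion)
  }
  if (capped) {
    add("ACE", "CH3", NA, NA, NA)
    add("ACE", "C", BB$b_ACE_CH3, NA, NA)
    add(1, "N", BB$b_C_N, BB$a_CH3_C_N, NA)
    add(1, "CA", BB$b_N_CA, BB$a_C_N_CA, 180)        # omega of the ACE amide
  } else {
    add(1, "N", NA, NA, NA)
    add(1, "CA", BB$b_N_CA, NA, NA)
  }
  for (i in seq_len(n_res)) {
    if (i == 1 && !capped) {
      add(1, "C", BB$b_CA_C, BB$a_N_CA_C, NA)
    } else {
      add(i, "C", BB$b_CA_C, BB$a_N_CA_C, phi)
    }
    if (i < n_res) {
      add(i + 1, "N", BB$b_C_N, BB$a_CA_C_N, psi)
      add(i + 1, "CA", BB$b_N_CA, BB$a_C_N_CA, 180)  # omega
    }
  }
  if (capped) {
    add("NME", "N", BB$b_C_N, BB$a_CA_C_N, psi)
    add("NME", "CH3", BB$b_NME_CH3, BB$a_C_N_CH3, 180)
  }

  # seed the first three chain atoms in the xy-plane, then extend
  p1 <- c(0, 0, 0)
  p2 <- c(chain[[2]]$bond, 0, 0)
  a3 <- deg(if (is.na(chain[[3]]$angle)) BB$a_N_CA_C else chain[[3]]$angle)
  p3 <- p2 + chain[[3]]$bond * c(-cos(a3), sin(a3), 0)
  put(chain[[1]]$slot, chain[[1]]$name, p1)
  put(chain[[2]]$slot, chain[[2]]$name, p2)
  put(chain[[3]]$slot, chain[[3]]$name, p3)
  prev <- list(p1, p2, p3)
  if (length(chain) >= 4) {
    for (k in 4:length(chain)) {
      e <- chain[[k]]
      xyz <- place_atom(prev[[1]], prev[[2]], prev[[3]],
                        e$bond, e$angle, e$torsion)
      put(e$slot, e$name, xyz)
      prev <- list(prev[[2]], prev[[3]], xyz)
    }
  }

  # ---- carbonyl / cap oxygens ------------------------------------------
  if (capped) {
    put("ACE", "O", place_atom(get_xyz(1, "CA"), get_xyz(1, "N"),
                               get_xyz("ACE", "C"),
                               BB$b_C_O, BB$a_O_C_N, 0))
  }
  for (i in seq_len(n_res)) {
    c_i <- get_xyz(i, "C"); ca_i <- get_xyz(i, "CA"); n_i <- get_xyz(i, "N")
    if (i < n_res || capped) {
      put(i, "O", place_atom(n_i, ca_i, c_i, BB$b_C_O, BB$a_CA_C_O, psi + 180))
    } else {
      put(i, "O", place_atom(n_i, ca_i, c_i, BB$b_C_OX, BB$a_CA_C_O, psi + 180))
      put(i, "OXT", place_atom(n_i, ca_i, c_i, BB$b_C_OX, BB$a_CA_C_O, psi))
    }
  }

  # ---- side chains ------------------------------------------------------
  for (i in seq_len(n_res)) {
    rn <- res3[[i]]
    if (rn != "GLY") {
      put(i, "CB", place_atom(get_xyz(i, "C"), get_xyz(i, "N"),
                              get_xyz(i, "CA"), 0.1530, 110.5, -122))
    }
    tmpl <- SIDE_CHAINS[[rn]]
    if (!is.null(tmpl)) {
      for (k in seq_len(nrow(tmpl))) {
        row <- tmpl[k, ]
        put(i, row$name,
            place_atom(get_xyz(i, row$tref), get_xyz(i, row$aref),
                       get_xyz(i, row$p), row$b, row$a, row$t))
      }
    }
  }

  # ---- assemble atom table in residue order -----------------------------
  residue_atoms <- function(slot, resname) {
    if (resname == "ACE") nm <- c("CH3", "C", "O")
    else if (resname %in% c("NME", "NMA")) nm <- c("N", "CH3")
    else {
      nm <- c("N", "CA", "C", "O")
      if (resname != "GLY") nm <- c(nm, "CB")
      if (!is.null(SIDE_CHAINS[[resname]])) nm <- c(nm, SIDE_CHAINS[[resname]]$name)
      if (!capped && slot == n_res) nm <- c(nm, "OXT")
    }
    nm
  }
  slots <- if (capped) c(list("ACE"), as.list(seq_len(n_res)), list("NME"))
           else as.list(seq_len(n_res))
  resnames <- if (capped) c("ACE", unname(res3), "NME") else unname(res3)

  rows <- list()
  serial <- 0L
  for (j in seq_along(slots)) {
    for (nm in residue_atoms(slots[[j]], resnames[[j]])) {
      xyz <- get_xyz(slots[[j]], nm)
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, element = guess_element(nm),
        resname = resnames[[j]], resid = j, chain = "A",
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows))
}

#' Build the N-methylacetamide (NMA) reference solute
#'
#' The minimal backbone mimic (CH3-CO-NH-CH3) used as the reference when
#' subtracting cap contributions in the hydrodiffusivity-scale derivation.
#' Built from the same ideal amide geometry as the peptide caps.
#'
#' @return A `ride_structure` with 5 heavy atoms.
#' @export
build_nma <- function() {
  ch3a <- c(0, 0, 0)
  cc <- c(BB$b_ACE_CH3, 0, 0)
  a <- deg(BB$a_CH3_C_N)
  n <- cc + BB$b_C_N * c(-cos(a), sin(a), 0)
  ch3n <- place_atom(ch3a, cc, n, BB$b_NME_CH3, BB$a_C_N_CH3, 180)
  o <- place_atom(ch3n, n, cc, BB$b_C_O, BB$a_O_C_N, 0)
  atoms <- data.frame(
    serial = 1:5,
    name = c("CH3", "C", "O", "N", "CH3"),
    element = c("C", "C", "O", "N", "C"),
    resname = "NMA", resid = 1L, chain = "A",
    x = c(ch3a[1], cc[1], o[1], n[1], ch3n[1]),
    y = c(ch3a[2], cc[2], o[2], n[2], ch3n[2]),
    z = c(ch3a[3], cc[3], o[3], n[3], ch3n[3]),
    stringsAsFactors = FALSE
  )
  new_structure(atoms)
}

#' Generate a cubic-grid cluster of identical spheres
#'
#' Pseudo-atom substrate for surface-area tests: `n` spheres of the given
#' radius on a cubic grid with the given spacing. Residue records are
#' synthetic one-atom glycines so that structure invariants hold; the radius
#' is set directly so no radius assignment is needed.
#'
#' @param n Number of spheres.
#' @param radius Sphere radius, nm.
#' @param spacing Grid spacing, nm.
#' @return A `ride_structure` with `radius` pre-assigned.
#' @export
gen_sphere_cluster <- function(n, radius, spacing) {
  stopifnot(n >= 1, radius > 0, spacing > 0)
  side <- ceiling(n^(1 / 3))
  idx <- 0:(side^3 - 1)
  gx <- idx %% side
  gy <- (idx %/% side) %% side
  gz <- idx %/% (side^2)
  atoms <- data.frame(
    serial = seq_len(n), name = "C", element = "C",
    resname = "GLY", resid = seq_len(n), chain = "A",
    x = gx[seq_len(n)] * spacing,
    y = gy[seq_len(n)] * spacing,
    z = gz[seq_len(n)] * spacing,
    stringsAsFactors = FALSE
  )
  s <- new_structure(atoms)
  s$atoms$radius <- radius
  s
}

#' Generate a Brownian trajectory with known diffusion coefficient
#'
#' Cumulative Gaussian steps with per-axis step variance 2 D dt, giving a
#' free random walk whose MSD expectation is 6 D tau in three dimensions.
#' Deterministic for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param D Diffusion coefficient, nm^2 ns^-1.
#' @param n_steps Number of steps (frames = n_steps + 1).
#' @param dt Time step, ps.
#' @param seed Integer RNG seed.
#' @return A `ride_trajectory`: list with `times` (ps), `positions`
#'   (frames x 3 matrix, nm, unwrapped) and `label`.
#' @export
gen_brownian_trajectory <- function(D, n_steps, dt, seed = 1L) {
  stopifnot(D >= 0, n_steps >= 1, dt > 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sd_step <- sqrt(2 * (D * 1e-3) * dt)  # D in nm^2/ps
  steps <- matrix(stats::rnorm(3 * n_steps, sd = sd_step), ncol = 3)
  pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  traj <- list(times = (0:n_steps) * dt, positions = pos,
               label = sprintf("brownian D=%g nm^2/ns seed=%d", D, seed))
  class(traj) <- "ride_trajectory"
  traj
}

#' Generate a finite-size diffusion series with known parameters
#'
#' Evaluates the cubic-cell finite-size relation at each box length and adds
#' optional seeded Gaussian noise, for exercising the 1/L extrapolation.
#'
#' @param D0 Infinite-dilution diffusion coefficient, 1e-5 cm^2 s^-1.
#' @param alpha Finite-size correction factor.
#' @param temperature K.
#' @param viscosity mPa s.
#' @param Ls Box edge lengths, nm.
#' @param noise_sd Gaussian noise sd on D_app (same units as D0); 0 = none.
#' @param seed Integer RNG seed (used only when `noise_sd > 0`).
#' @return A `ride_fs_series`: list with `entries` (data.frame `L`, `Dapp`,
#'   `err`), `temperature`, `viscosity`.
#' @export
gen_finite_size_series <- function(D0, alpha, temperature, viscosity, Ls,
                                   noise_sd = 0, seed = 1L) {
  stopifnot(D0 > 0, temperature > 0, viscosity > 0, length(Ls) >= 1,
            all(Ls > 0), noise_sd >= 0)
  dapp <- vapply(Ls, function(L)
    finite_size_D(D0, L, temperature, viscosity, alpha), numeric(1))
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    dapp <- dapp + stats::rnorm(length(Ls), sd = noise_sd)
  }
  fs <- list(
    entries = data.frame(L = Ls, Dapp = dapp,
                         err = if (noise_sd > 0) rep(noise_sd, length(Ls))
                               else rep(NA_real_, length(Ls))),
    temperature = temperature, viscosity = viscosity
  )
  class(fs) <- "ride_fs_series"
  fs
}
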