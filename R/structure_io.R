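# structure_io: read/write molecular structures and MSMS-style per-atom
# area files; residue bookkeeping, terminus detection, mass computation,
# and per-residue-type area accumulation.
#
# Coordinates are stored in nm internally; PDB files are Angstrom-native and
# converted on the way in/out.

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by [read_pdb()] and the fixture builders. The
#' atom table must contain one row per atom with columns `serial`, `name`,
#' `element`, `resname`, `resid`, `chain`, `x`, `y`, `z` (nm). A `radius`
#' column (nm) is optional and may be filled later with [assign_radii()].
#'
#' @param atoms data.frame as described above.
#' @return A `ride_structure` object: list with `atoms`, `residues`
#'   (one row per residue: `resname`, `resid`, `chain`, `is_cap`, atom span),
#'   `terminus_mode` (`"capped"` or `"zwitterionic"`) and `sequence`
#'   (1-letter string over the standard residues, caps excluded).
#' @export
new_structure <- function(atoms) {
  required <- c("serial", "name", "element", "resname", "resid", "chain",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    bad <- which(!stats::complete.cases(atoms[, c("x", "y", "z")]) |
                   !is.finite(atoms$x + atoms$y + atoms$z))
    stop("non-finite coordinates for atom serial(s): ",
         paste(utils::head(atoms$serial[bad], 5), collapse = ", "))
  }
  atoms$resname <- toupper(atoms$resname)
  if (!("radius" %in% names(atoms))) atoms$radius <- NA_real_

  unknown <- setdiff(unique(atoms$resname), c(AA3, CAP_RESIDUES))
  if (length(unknown) > 0) {
    stop("unrecognized residue name(s): ", paste(unknown, collapse = ", "),
         " (only the 20 standard amino acids and ACE/NME/NMA caps are supported)")
  }

  # residues in order of first appearance of (chain, resid)
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  first_idx <- which(!duplicated(key))
  residues <- data.frame(
    resname = atoms$resname[first_idx],
    resid = atoms$resid[first_idx],
    chain = atoms$chain[first_idx],
    stringsAsFactors = FALSE
  )
  residues$is_cap <- residues$resname %in% CAP_RESIDUES
  residues$first <- first_idx
  residues$last <- c(first_idx[-1] - 1L, nrow(atoms))

  std <- residues$resname[!residues$is_cap]
  s <- list(
    atoms = atoms,
    residues = residues,
    sequence = paste(AA1[std], collapse = ""),
    terminus_mode = NA_character_
  )
  class(s) <- "ride_structure"
  s$terminus_mode <- detect_termini(s)
  s
}

#' @export
print.ride_structure <- function(x, ...) {
  cat(sprintf("<ride_structure> %d atoms, %d residues (%s), termini: %s\n",
              nrow(x$atoms), nrow(x$residues),
              if (nzchar(x$sequence)) x$sequence else "-",
              x$terminus_mode))
  invisible(x)
}

#' Read a PDB structure file
#'
#' Parses ATOM/HETATM records (via bio3d), converts coordinates from
#' Angstrom to nm, and builds the residue bookkeeping used throughout the
#' package. ACE/NME/NMA cap groups are retained and flagged as caps. Waters
#' and monatomic ions among HETATM records are dropped by default. Where
#' alternate locations are present, the first is taken.
#'
#' @param path Path to a PDB file.
#' @param keep_solvent Keep water/ion HETATM records (default `FALSE`).
#' @return A `ride_structure`; see [new_structure()].
#' @export
read_pdb <- function(path, keep_solvent = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  # first altloc wins
  if (!is.null(at$alt)) {
    alt_keep <- is.na(at$alt) | at$alt %in% c("", "A", "1")
    at <- at[alt_keep, , drop = FALSE]
  }
  if (!keep_solvent) {
    solvent <- c("HOH", "WAT", "SOL", "TIP", "NA", "CL", "K", "MG", "CA2",
                 "ZN", "SO4", "PO4")
    drop <- at$type == "HETATM" & toupper(at$resid) %in% solvent
    at <- at[!drop, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("empty structure after solvent filtering: ", path)
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad) > 0) {
    stop("malformed coordinate record near atom serial ",
         at$eleno[bad[1]], " in ", path)
  }
  element <- at$elesy
  if (is.null(element)) element <- rep("", nrow(at))
  element <- toupper(trimws(element))
  fallback <- guess_element(at$elety)
  element <- ifelse(is.na(element) | element == "", fallback, element)

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = element,
    resname = toupper(trimws(at$resid)),
    resid = as.integer(at$resno),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x / 10, y = at$y / 10, z = at$z / 10,  # Angstrom -> nm
    stringsAsFactors = FALSE
  )
  new_structure(atoms)
}

# Element symbol from a PDB atom name: first alphabetic character, which is
# correct for protein heavy atoms and hydrogens (avoids reading "CA" as
# calcium).
guess_element <- function(name) {
  toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(name))),
                 1, 1))
}

#' Write a structure to a PDB file
#'
#' Inverse of [read_pdb()]: coordinates are converted from nm back to
#' Angstrom. Round-tripping a structure through `write_pdb()`/[read_pdb()]
#' preserves coordinates to PDB format precision (1e-3 A).
#'
#' @param s A `ride_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "ride_structure"))
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]) * 10)),
    type = rep("ATOM", nrow(a)),
    eleno = a$serial,
    elety = a$name,
    resid = a$resname,
    chain = a$chain,
    resno = a$resid,
    elesy = a$element
  )
  invisible(path)
}

#' Detect the backbone terminus mode of a structure
#'
#' A structure is `"capped"` when both an acetyl (ACE) cap and an
#' N-methylamide (NME/NMA) cap are present; anything else -- including a
#' single orphan cap, for which a warning is raised -- is treated as a
#' zwitterionic backbone. The mode selects the terminus coefficient in the
#' hydrodynamic-radius assembly.
#'
#' @param s A `ride_structure`.
#' @return `"capped"` or `"zwitterionic"`.
#' @export
detect_termini <- function(s) {
  stopifnot(inherits(s, "ride_structure"))
  res <- s$residues$resname
  if (length(res) == 0) stop("structure has no residues")
  if (all(res %in% CAP_RESIDUES)) return("capped")  # bare cap fragment (NMA)
  has_ace <- "ACE" %in% res
  has_nme <- any(c("NME", "NMA") %in% res)
  if (has_ace && has_nme) return("capped")
  if (has_ace || has_nme) {
    warning("only one cap group present; treating backbone as zwitterionic")
  }
  "zwitterionic"
}

#' Read an MSMS-style per-atom area file
#'
#' Whitespace-delimited dialect: the first numeric column is the 1-based
#' atom index and the second is the solvent-excluded area of that atom in
#' Angstrom^2. Lines starting with `#` or whose first token is non-numeric
#' (headers) are skipped. Areas are converted to nm^2 and keyed by the
#' structure's atom serials in file order.
#'
#' @param path Path to the area file.
#' @param s The `ride_structure` the areas belong to; the number of data
#'   rows must equal the number of atoms.
#' @return A `ride_area_table`: list with `areas` (named numeric, nm^2, names
#'   are atom serials) and `source = "external_file"`.
#' @export
read_area_file <- function(path, s) {
  stopifnot(inherits(s, "ride_structure"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) strsplit(ln, "[[:space:]]+")[[1]])
  keep <- vapply(rows, function(tok) {
    length(tok) >= 2 && !is.na(suppressWarnings(as.numeric(tok[1])))
  }, logical(1))
  rows <- rows[keep]
  n_atoms <- nrow(s$atoms)
  if (length(rows) != n_atoms) {
    stop("area file has ", length(rows), " data rows but the structure has ",
         n_atoms, " atoms")
  }
  area_A2 <- vapply(rows, function(tok) as.numeric(tok[2]), numeric(1))
  if (any(!is.finite(area_A2))) stop("non-numeric area value in ", path)
  if (any(area_A2 < 0)) {
    stop("negative area value (", min(area_A2), " A^2) in ", path)
  }
  areas <- area_A2 * 0.01  # A^2 -> nm^2
  names(areas) <- as.character(s$atoms$serial)
  structure(list(areas = areas, source = "external_file"),
            class = "ride_area_table")
}

#' Write per-atom areas in the MSMS-style dialect
#'
#' Companion writer for [read_area_file()]: one row per atom, columns are
#' the 1-based atom index and the area in Angstrom^2, preceded by a `#`
#' header line.
#'
#' @param areas A `ride_area_table` or a [compute_sesa()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_area_file <- function(areas, path) {
  per_atom <- if (inherits(areas, "ride_sesa_result")) areas$per_atom
              else areas$areas
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# atom_index ses_area_A2", con)
  writeLines(sprintf("%d %.6f", seq_along(per_atom), per_atom * 100), con)
  invisible(path)
}

#' Convert a SESA result to an area table
#'
#' @param sesa A `ride_sesa_result` from [compute_sesa()].
#' @param s The structure the result was computed on.
#' @return A `ride_area_table` with `source = "internal"`.
#' @export
as_area_table <- function(sesa, s) {
  stopifnot(inherits(sesa, "ride_sesa_result"), inherits(s, "ride_structure"))
  areas <- sesa$per_atom
  names(areas) <- as.character(s$atoms$serial)
  structure(list(areas = areas, source = "internal"),
            class = "ride_area_table")
}

#' Molecular weight of a peptide structure
#'
#' Sum of standard residue masses; zwitterionic chains gain one water per
#' chain (the free termini), capped chains gain the ACE/NME cap masses via
#' their residue records. Matches the molar-mass convention of peptide
#' sequence calculators.
#'
#' @param s A `ride_structure`.
#' @return Molar mass in kg mol^-1.
#' @export
molecular_weight <- function(s) {
  stopifnot(inherits(s, "ride_structure"))
  res <- s$residues
  if (nrow(res) == 0) stop("empty structure")
  unknown <- setdiff(res$resname, names(RESIDUE_MASS))
  if (length(unknown) > 0) {
    stop("unknown residue(s) for mass computation: ",
         paste(unknown, collapse = ", "))
  }
  mass_g <- sum(RESIDUE_MASS[res$resname])
  if (s$terminus_mode == "zwitterionic") {
    mass_g <- mass_g + WATER_MASS * length(unique(res$chain))
  }
  mass_g / 1000
}

#' Accumulate per-atom SES areas by residue type
#'
#' Sums the solvent-excluded area of all atoms belonging to each of the 20
#' standard amino-acid types; cap-group atoms (ACE/NME/NMA) are accumulated
#' under a dedicated `"CAP"` key. The sum over the returned map equals the
#' total per-atom area, so area is conserved.
#'
#' @param s A `ride_structure`.
#' @param a A `ride_area_table` paired with `s`.
#' @return Named numeric vector (nm^2) over the 20 amino-acid types plus
#'   `"CAP"`; types absent from the structure map to 0.
#' @export
accumulate_sesa_by_restype <- function(s, a) {
  stopifnot(inherits(s, "ride_structure"), inherits(a, "ride_area_table"))
  if (length(a$areas) != nrow(s$atoms)) {
    stop("area table has ", length(a$areas), " entries but the structure has ",
         nrow(s$atoms), " atoms")
  }
  type <- ifelse(s$atoms$resname %in% CAP_RESIDUES, "CAP", s$atoms$resname)
  sums <- tapply(unname(a$areas), type, sum)
  out <- stats::setNames(numeric(length(AA3) + 1), c(AA3, "CAP"))
  out[names(sums)] <- as.numeric(sums)
  out
}
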