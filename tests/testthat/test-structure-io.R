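# structure reading/writing, residue bookkeeping, area files, masses

test_that("a hand-written ALA fragment parses atom by atom", {
  path <- write_raw_pdb(c(
    pdb_atom_line(1, "N", "ALA", 1, 1.000, 2.000, 3.000, "N"),
    pdb_atom_line(2, "CA", "ALA", 1, 2.458, 2.000, 3.000, "C"),
    pdb_atom_line(3, "C", "ALA", 1, 3.010, 3.420, 3.000, "C"),
    pdb_atom_line(4, "O", "ALA", 1, 2.300, 4.440, 3.000, "O"),
    pdb_atom_line(5, "CB", "ALA", 1, 3.010, 0.800, 3.000, "C"),
    "END"))
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 5)
  expect_equal(nrow(s$residues), 1)
  expect_equal(s$sequence, "A")
  expect_equal(s$atoms$x[1], 0.1)  # Angstrom -> nm
  expect_equal(s$atoms$name, c("N", "CA", "C", "O", "CB"))
  expect_equal(s$terminus_mode, "zwitterionic")
})

test_that("cap residues are retained but excluded from the sequence", {
  path <- write_raw_pdb(c(
    pdb_atom_line(1, "CH3", "ACE", 1, 0, 0, 0, "C"),
    pdb_atom_line(2, "C", "ACE", 1, 1.5, 0, 0, "C"),
    pdb_atom_line(3, "N", "ALA", 2, 2.2, 1.1, 0, "N"),
    pdb_atom_line(4, "CA", "ALA", 2, 3.6, 1.2, 0, "C"),
    pdb_atom_line(5, "C", "ALA", 2, 4.3, 2.5, 0, "C"),
    pdb_atom_line(6, "N", "NME", 3, 5.6, 2.5, 0, "N"),
    pdb_atom_line(7, "CH3", "NME", 3, 6.4, 3.7, 0, "C"),
    "END"))
  s <- read_pdb(path)
  expect_equal(nrow(s$residues), 3)
  expect_equal(s$sequence, "A")
  expect_equal(s$terminus_mode, "capped")
})

test_that("write_pdb / read_pdb round-trips coordinates to format precision", {
  s <- build_peptide("ACDEFGHIKL", "extended", capped = TRUE)
  path <- tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                      as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_equal(s2$sequence, s$sequence)
  expect_equal(s2$terminus_mode, "capped")
})

test_that("unrecognized residues and empty structures are rejected", {
  path <- write_raw_pdb(c(pdb_atom_line(1, "C1", "LIG", 1, 0, 0, 0, "C"), "END"))
  expect_error(read_pdb(path), "unrecognized residue")
  expect_error(read_pdb(write_raw_pdb("END")), "")
  expect_error(new_structure(data.frame()), "missing columns")
})

test_that("terminus detection is rule-based and order-invariant", {
  expect_equal(build_peptide("A", capped = TRUE)$terminus_mode, "capped")
  expect_equal(build_peptide("ADKF", capped = FALSE)$terminus_mode,
               "zwitterionic")
  # one orphan cap: conservative zwitterionic with a warning
  s <- build_peptide("A", capped = TRUE)
  atoms <- s$atoms[s$atoms$resname != "NME", ]
  expect_warning(s1 <- new_structure(atoms), "one cap")
  expect_equal(s1$terminus_mode, "zwitterionic")
  # atom order within residues does not matter
  s2 <- build_peptide("AG", capped = TRUE)
  perm <- unlist(lapply(split(seq_len(nrow(s2$atoms)), s2$atoms$resid),
                        function(ix) rev(ix)), use.names = FALSE)
  s3 <- new_structure(s2$atoms[perm, ])
  expect_equal(s3$terminus_mode, s2$terminus_mode)
})

test_that("area files parse with unit conversion, headers and strict counts", {
  s <- gen_sphere_cluster(2, 0.15, 1)
  path <- tempfile()
  writeLines(c("1 10.0", "2 20.0"), path)
  at <- read_area_file(path, s)
  expect_equal(unname(at$areas), c(0.10, 0.20))
  expect_equal(at$source, "external_file")

  writeLines(c("# comment", "atom area extra", "1 10.0 9 9", "2 20.0 9 9"), path)
  expect_equal(unname(read_area_file(path, s)$areas), c(0.10, 0.20))

  writeLines(c("1 10.0"), path)
  expect_error(read_area_file(path, s), "1 data rows.*2 atoms")
  writeLines(c("1 10.0", "2 -3.0"), path)
  expect_error(read_area_file(path, s), "negative")
})

test_that("internal SESA exported to the area dialect re-reads identically", {
  s <- assign_radii(build_peptide("AG", capped = TRUE))
  res <- compute_sesa(s, quick_sesa())
  path <- tempfile()
  write_area_file(res, path)
  at <- read_area_file(path, s)
  expect_equal(unname(at$areas), res$per_atom, tolerance = 1e-7)
})

test_that("molecular weights follow the residue-mass convention", {
  expect_equal(molecular_weight(build_peptide("AAA", capped = FALSE)) * 1000,
               3 * 71.0788 + 18.0153, tolerance = 1e-6)
  expect_equal(molecular_weight(build_peptide("G", capped = FALSE)) * 1000,
               75.07, tolerance = 1e-3)
  # capped peptide: cap masses, no free water
  expect_equal(molecular_weight(build_peptide("A", capped = TRUE)) * 1000,
               43.0446 + 71.0788 + 30.0493, tolerance = 1e-6)
})

test_that("per-type accumulation is additive, conserving and CAP-separated", {
  s <- build_peptide("AA", capped = FALSE)
  n_atoms <- nrow(s$atoms)
  # hand-assigned residue areas 0.3 and 0.4 nm^2
  areas <- numeric(n_atoms)
  areas[s$atoms$resid == 1] <- 0.3 / sum(s$atoms$resid == 1)
  areas[s$atoms$resid == 2] <- 0.4 / sum(s$atoms$resid == 2)
  at <- structure(list(areas = setNames(areas, s$atoms$serial),
                       source = "external_file"), class = "ride_area_table")
  ta <- accumulate_sesa_by_restype(s, at)
  expect_equal(ta[["ALA"]], 0.7)
  expect_equal(sum(ta), 0.7)

  # zero table -> all zeros
  at0 <- structure(list(areas = setNames(numeric(n_atoms), s$atoms$serial),
                        source = "external_file"), class = "ride_area_table")
  expect_true(all(accumulate_sesa_by_restype(s, at0) == 0))

  # mixed sequence vs brute-force per-atom grouping, caps under CAP
  s2 <- assign_radii(build_peptide("AGA", capped = TRUE))
  res <- compute_sesa(s2, quick_sesa())
  at2 <- as_area_table(res, s2)
  ta2 <- accumulate_sesa_by_restype(s2, at2)
  brute <- tapply(res$per_atom,
                  ifelse(s2$atoms$resname %in% c("ACE", "NME", "NMA"),
                         "CAP", s2$atoms$resname), sum)
  for (k in names(brute)) expect_equal(ta2[[k]], unname(brute[k]))
  expect_equal(sum(ta2), res$total, tolerance = 1e-9)
  expect_gt(ta2[["CAP"]], 0)
})
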