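# Stokes radii, hydrodiffusivity coefficients, scale building and assembly

test_that("stokes_radius matches the closed form and scales inversely with D", {
  d <- diffusion_estimate(3.32, 310.15, 0.275)
  expect_equal(stokes_radius(d), 0.2488, tolerance = 1e-3)
  d2 <- diffusion_estimate(2.44, 310.15, 0.275)
  expect_equal(stokes_radius(d2), 0.3386, tolerance = 1e-3)
  # exact closed form
  kB <- ride_constants$k_B
  expect_equal(stokes_radius(d),
               kB * 310.15 / (6 * pi * 0.275e-3 * 3.32e-9) * 1e9)
  # inverse proportionality
  dd <- diffusion_estimate(2 * 3.32, 310.15, 0.275)
  expect_equal(stokes_radius(dd), stokes_radius(d) / 2)
  expect_error(diffusion_estimate(-1, 310, 0.3), "must be > 0")
})

test_that("stokes_einstein_D is the exact inverse of stokes_radius", {
  d <- diffusion_estimate(2.44, 310.15, 0.275)
  back <- stokes_einstein_D(stokes_radius(d), 310.15, 0.275)
  expect_equal(back$value, d$value, tolerance = 1e-12)
  expect_equal(stokes_einstein_D(0.2488, 310.15, 0.275)$value, 3.32,
               tolerance = 1e-3)
  # doubling viscosity halves D
  expect_equal(stokes_einstein_D(0.25, 310.15, 0.55)$value,
               stokes_einstein_D(0.25, 310.15, 0.275)$value / 2)
  expect_error(stokes_einstein_D(-0.1, 310, 0.3), "> 0")
})

test_that("coefficient derivation follows the squared-radius ratio", {
  ref <- diffusion_estimate(3.32, 310.15, 0.275)
  cap <- diffusion_estimate(2.44, 310.15, 0.275)
  # zero area difference is an error
  expect_error(derive_coefficient(cap, 1.0, ref, 1.0), "exceed")
  # mismatched conditions are an error
  ref2 <- diffusion_estimate(3.32, 298.15, 0.275)
  expect_error(derive_coefficient(cap, 2, ref2, 1), "different conditions")
  # synthetic: dR^2 = 0.05, dA = 0.5 -> 0.10
  r_ref <- stokes_radius(ref)
  d_cap <- stokes_einstein_D(sqrt(r_ref^2 + 0.05), 310.15, 0.275)
  expect_equal(derive_coefficient(d_cap, 1.5, ref, 1.0), 0.10,
               tolerance = 1e-10)
  # algebraic inversion pinned to the printed monopeptide ALA convention
  dr2 <- stokes_radius(cap)^2 - stokes_radius(ref)^2
  expect_equal(derive_coefficient(cap, 1 + dr2 / 0.0757, ref, 1), 0.0757,
               tolerance = 1e-12)
})

test_that("equal inputs give equal coefficients and the zwit terminus rule", {
  # stub area provider: every cap atom carries a fixed share, every residue
  # bucket integrates to the same area, so equal D must give equal C
  d_equal <- setNames(lapply(1:20, function(i)
    diffusion_estimate(2.2, 310.15, 0.275)), ride:::AA3)
  nma <- nma_diffusion()
  provider <- function(s) {
    is_cap <- s$atoms$resname %in% c("ACE", "NME", "NMA")
    per_atom <- numeric(nrow(s$atoms))
    per_atom[is_cap] <- 0.9 / 5
    if (any(!is_cap)) per_atom[!is_cap] <- 1.3 / sum(!is_cap)
    structure(list(per_atom = per_atom, total = sum(per_atom),
                   params = quick_sesa()), class = "ride_sesa_result")
  }
  sc <- build_scale(d_equal, nma, "M", area_provider = provider)
  expect_equal(unname(diff(range(sc$coefficients))), 0, tolerance = 1e-12)
  expect_equal(sc$C_term_zwit,
               mean(c(sc$coefficients[["ASP"]], sc$coefficients[["LYS"]])))
  expect_equal(sc$SESA_term, 0.9)
  expect_equal(sc$C_term_capped, stokes_radius(nma)^2 / 0.9)
  # missing amino acid is an error
  expect_error(build_scale(d_equal[-1], nma, "M", area_provider = provider),
               "missing amino acid")
})

test_that("assembly is the algebraic inverse on degenerate and scaled input", {
  sc <- ride_scale("M")
  zero <- setNames(numeric(20), ride:::AA3)
  # all-zero areas reproduce the terminus anchor R_H of NMA
  expect_equal(assemble_hydrodynamic_radius(zero, sc, "capped"),
               sqrt(sc$C_term_capped * sc$SESA_term))
  expect_equal(sqrt(sc$C_term_capped * sc$SESA_term),
               stokes_radius(nma_diffusion()), tolerance = 1e-9)
  # linearity: doubling areas doubles R^2 - terminus term
  areas <- setNames(runif(20, 0, 0.5), ride:::AA3)
  r1 <- assemble_hydrodynamic_radius(areas, sc, "capped")
  r2 <- assemble_hydrodynamic_radius(2 * areas, sc, "capped")
  term <- sc$C_term_capped * sc$SESA_term
  expect_equal((r2^2 - term) / (r1^2 - term), 2, tolerance = 1e-12)
  # monotonicity: increasing any area increases R_H (decreases D)
  areas2 <- areas; areas2[["TRP"]] <- areas2[["TRP"]] + 0.1
  expect_gt(assemble_hydrodynamic_radius(areas2, sc, "capped"), r1)
  expect_error(assemble_hydrodynamic_radius(-areas, sc, "capped"), "negative")
})

test_that("shipped-scale round trip reproduces the reference diffusion", {
  # self-consistency by construction: assembling the derivation structure's
  # own areas must return the tabulated simulation D_0
  sc <- ride_scale("M")
  tab <- peptide_diffusion_table()
  for (aa in c("GLY", "ALA", "TRP")) {
    s <- build_peptide(ride:::AA1[[aa]], "extended", capped = TRUE)
    p <- ride_predict(s, sc)
    expect_equal(p$D0$value, tab$D0_mono[tab$aa == aa], tolerance = 0.005)
  }
})

test_that("scale files round-trip through the text format", {
  sc <- ride_scale("M")
  path <- tempfile(fileext = ".tsv")
  write_hydro_scale(sc, path)
  sc2 <- read_hydro_scale(path)
  expect_equal(sc2$coefficients, sc$coefficients, tolerance = 1e-9)
  expect_equal(sc2$C_term_capped, sc$C_term_capped, tolerance = 1e-9)
  expect_equal(sc2$C_term_zwit, sc$C_term_zwit, tolerance = 1e-9)
  expect_equal(sc2$SESA_term, sc$SESA_term, tolerance = 1e-9)
  expect_equal(sc2$variant, sc$variant)
  expect_equal(sc2$temperature, sc$temperature)
  expect_equal(sc2$radius_set_name, sc$radius_set_name)
})

test_that("the derived ALA coefficient sits near the published anchor", {
  # re-derive only C_ALA (fast path of the full scale build)
  prm <- sesa_params(0.15, 400)
  ala <- compute_sesa(assign_radii(build_peptide("A", "extended", TRUE)), prm)
  nma_s <- assign_radii(build_nma())
  nma_area <- compute_sesa(nma_s, prm)$total
  s <- build_peptide("A", "extended", TRUE)
  ta <- accumulate_sesa_by_restype(s, structure(
    list(areas = setNames(ala$per_atom, s$atoms$serial), source = "internal"),
    class = "ride_area_table"))
  solute_area <- ala$total - ta[["CAP"]]
  C <- derive_coefficient(diffusion_estimate(2.44, 310.15, 0.275),
                          solute_area + nma_area,
                          nma_diffusion(), nma_area)
  expect_equal(C, 0.0757, tolerance = 0.15)
  expect_equal(ride_scale("M")$coefficients[["ALA"]], C, tolerance = 1e-6)
})
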