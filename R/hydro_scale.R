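# hydro_scale: Stokes radii from diffusion coefficients, unitless
# hydrodiffusivity coefficients C = dR_H^2 / dSESA, and additive assembly of
# a hydrodynamic radius from per-residue-type surface areas.

#' Construct a diffusion-coefficient estimate
#'
#' Carrier for a diffusion coefficient together with the thermodynamic state
#' it refers to.
#'
#' @param value Diffusion coefficient, 1e-5 cm^2 s^-1.
#' @param temperature K (may be `NA` when unknown, e.g. a bare MSD fit).
#' @param viscosity mPa s (may be `NA`).
#' @param uncertainty Optional 1-sigma uncertainty, same units as `value`.
#' @param kind One of `"D_app"`, `"D_0"`, `"D_eta"`, `"predicted"`.
#' @return A `ride_diffusion` object.
#' @export
diffusion_estimate <- function(value, temperature = NA_real_,
                               viscosity = NA_real_,
                               uncertainty = NA_real_, kind = "D_0") {
  stopifnot(is.numeric(value), length(value) == 1)
  if (!is.finite(value) || value <= 0) stop("diffusion coefficient must be > 0")
  if (!is.na(temperature) && temperature <= 0) stop("temperature must be > 0")
  if (!is.na(viscosity) && viscosity <= 0) stop("viscosity must be > 0")
  kind <- match.arg(kind, c("D_app", "D_0", "D_eta", "predicted"))
  d <- list(value = value, uncertainty = uncertainty,
            temperature = temperature, viscosity = viscosity, kind = kind)
  class(d) <- "ride_diffusion"
  d
}

#' @export
print.ride_diffusion <- function(x, ...) {
  cat(sprintf("<%s> %.4g x 1e-5 cm^2/s (T = %s K, eta = %s mPa s)\n",
              x$kind, x$value,
              format(x$temperature), format(x$viscosity)))
  invisible(x)
}

#' Stokes (hydrodynamic) radius from a diffusion coefficient
#'
#' R_H = k_B T / (6 pi eta D), the Stokes-Einstein relation rearranged for
#' the radius.
#'
#' @param d A `ride_diffusion` with temperature and viscosity set.
#' @return Hydrodynamic radius in nm.
#' @export
stokes_radius <- function(d) {
  stopifnot(inherits(d, "ride_diffusion"))
  if (is.na(d$temperature) || is.na(d$viscosity)) {
    stop("diffusion estimate lacks temperature or viscosity")
  }
  k <- ride_constants
  r_m <- k$k_B * d$temperature /
    (6 * pi * d$viscosity * k$eta_unit * d$value * k$D_unit)
  r_m / k$length_unit
}

#' Diffusion coefficient from a hydrodynamic radius
#'
#' The Stokes-Einstein relation D = k_B T / (6 pi eta R_H); exact inverse of
#' [stokes_radius()].
#'
#' @param R_H Hydrodynamic radius, nm.
#' @param temperature K.
#' @param viscosity mPa s.
#' @param kind Kind tag for the returned estimate (default `"D_0"`).
#' @return A `ride_diffusion` in 1e-5 cm^2 s^-1.
#' @export
stokes_einstein_D <- function(R_H, temperature, viscosity, kind = "D_0") {
  stopifnot(is.numeric(R_H), length(R_H) == 1)
  if (R_H <= 0 || temperature <= 0 || viscosity <= 0) {
    stop("R_H, temperature and viscosity must all be > 0")
  }
  k <- ride_constants
  d_m2s <- k$k_B * temperature /
    (6 * pi * viscosity * k$eta_unit * R_H * k$length_unit)
  diffusion_estimate(d_m2s / k$D_unit, temperature, viscosity, kind = kind)
}

#' Derive a hydrodiffusivity coefficient
#'
#' The unitless coefficient of a solute, from the squared-radius and
#' surface-area differences between its capped form and the NMA reference:
#' C = (R_H,capped^2 - R_H,ref^2) / (SESA_capped - SESA_ref). Both diffusion
#' estimates must refer to the same temperature and viscosity.
#'
#' @param capped_D `ride_diffusion` of the capped solute.
#' @param capped_area Total SESA of the capped solute, nm^2.
#' @param ref_D `ride_diffusion` of the reference (NMA).
#' @param ref_area Total SESA of the reference, nm^2.
#' @return Unitless coefficient C > 0.
#' @export
derive_coefficient <- function(capped_D, capped_area, ref_D, ref_area) {
  stopifnot(inherits(capped_D, "ride_diffusion"),
            inherits(ref_D, "ride_diffusion"))
  if (!isTRUE(all.equal(capped_D$temperature, ref_D$temperature)) ||
      !isTRUE(all.equal(capped_D$viscosity, ref_D$viscosity))) {
    stop("capped and reference estimates are at different conditions")
  }
  dr2 <- stokes_radius(capped_D)^2 - stokes_radius(ref_D)^2
  da <- capped_area - ref_area
  if (da <= 0) stop("capped area must exceed the reference area")
  if (dr2 <= 0) {
    stop("capped solute has no excess hydrodynamic radius over the reference; ",
         "physically inconsistent input")
  }
  dr2 / da
}

#' Build a hydrodiffusivity scale
#'
#' Derives the full per-amino-acid coefficient set from a table of
#' simulation diffusion coefficients plus internally generated fixture
#' structures: capped extended monopeptides for the `"M"` variant, capped
#' helical homo-decapeptides for the `"D"` variant (polyproline helix for
#' PRO). Terminus parameters follow the scale definition: the capped
#' terminus coefficient is the NMA coefficient R_H,NMA^2 / SESA_NMA; the
#' zwitterionic terminus coefficient is the mean of the ASP and LYS
#' coefficients (the two formally charged pH-7 side-chain archetypes); the
#' terminus reference area is the SESA of NMA in both modes.
#'
#' @param d_table Named list of `ride_diffusion` over the 20 amino-acid
#'   3-letter codes, all at one (T, eta).
#' @param nma_D `ride_diffusion` of N-methylacetamide at the same state.
#' @param variant `"M"` (monopeptide) or `"D"` (decapeptide).
#' @param params SESA parameters used for the fixture areas.
#' @param radius_set Radius set used for the fixture areas.
#' @param area_provider Function `structure -> ride_sesa_result`; defaults to
#'   the internal SESA engine with `params`/`radius_set`. Exposed so an
#'   external area source can stand in.
#' @return A `ride_hydro_scale` object.
#' @export
build_scale <- function(d_table, nma_D, variant = c("M", "D"),
                        params = sesa_params(),
                        radius_set = default_radius_set(),
                        area_provider = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(nma_D, "ride_diffusion"))
  missing_aa <- setdiff(AA3, names(d_table))
  if (length(missing_aa) > 0) {
    stop("d_table is missing amino acid(s): ", paste(missing_aa, collapse = ", "))
  }
  if (is.null(area_provider)) {
    area_provider <- function(s) compute_sesa(assign_radii(s, radius_set), params)
  }
  nma_area <- area_provider(build_nma())$total

  coeffs <- stats::setNames(numeric(length(AA3)), AA3)
  for (aa in AA3) {
    d <- d_table[[aa]]
    stopifnot(inherits(d, "ride_diffusion"))
    seq1 <- AA1[[aa]]
    if (variant == "M") {
      s <- build_peptide(seq1, "extended", capped = TRUE)
    } else {
      conf <- if (aa == "PRO") "polyproline" else "alpha_helix"
      s <- build_peptide(strrep(seq1, 10), conf, capped = TRUE)
    }
    # The coefficient denominator is the residue-owned surface of the capped
    # fixture (total minus the cap atoms' accumulated area): the cap surface
    # is represented in the assembly by the constant terminus term, so this
    # choice makes assemble_hydrodynamic_radius the exact algebraic inverse
    # of the derivation on the derivation structures.
    sesa_res <- area_provider(s)
    type_areas <- accumulate_sesa_by_restype(s, as_area_table(sesa_res, s))
    solute_area <- sesa_res$total - type_areas[["CAP"]]
    coeffs[[aa]] <- derive_coefficient(d, solute_area + nma_area, nma_D, nma_area)
  }
  scale <- list(
    variant = variant,
    coefficients = coeffs,
    C_term_capped = stokes_radius(nma_D)^2 / nma_area,
    C_term_zwit = mean(c(coeffs[["ASP"]], coeffs[["LYS"]])),
    SESA_term = nma_area,
    radius_set_name = radius_set$name,
    temperature = nma_D$temperature,
    viscosity = nma_D$viscosity,
    probe_radius = params$probe_radius,
    n_points = params$n_points,
    conformation = if (variant == "M") "extended" else "alpha_helix"
  )
  class(scale) <- "ride_hydro_scale"
  scale
}

#' @export
print.ride_hydro_scale <- function(x, ...) {
  cat(sprintf(
    "<ride_hydro_scale> variant %s, T = %.2f K, eta = %.3f mPa s, radii '%s'\n",
    x$variant, x$temperature, x$viscosity, x$radius_set_name))
  cat(sprintf("  C range [%.4f, %.4f]; C_term capped %.4f / zwit %.4f; SESA_term %.4f nm^2\n",
              min(x$coefficients), max(x$coefficients),
              x$C_term_capped, x$C_term_zwit, x$SESA_term))
  invisible(x)
}

#' Assemble a hydrodynamic radius from per-type surface areas
#'
#' The additive radius assembly: R_H,total^2 = C_term SESA_term +
#' sum_i C_i SESA_i over the 20 amino-acid types, with the terminus
#' coefficient selected by the backbone mode and SESA_term the scale's
#' stored NMA reference area. Any `"CAP"` entry of the area map is ignored:
#' cap/terminus contributions enter only through the constant term.
#'
#' @param type_areas Named numeric (nm^2) over amino-acid types, as returned
#'   by [accumulate_sesa_by_restype()].
#' @param scale A `ride_hydro_scale`.
#' @param mode `"capped"` or `"zwitterionic"`.
#' @return Total hydrodynamic radius, nm.
#' @export
assemble_hydrodynamic_radius <- function(type_areas, scale,
                                         mode = c("capped", "zwitterionic")) {
  stopifnot(inherits(scale, "ride_hydro_scale"))
  mode <- match.arg(mode)
  aa_present <- intersect(names(type_areas), AA3)
  areas <- type_areas[aa_present]
  if (any(areas < 0)) stop("negative per-type area")
  c_term <- if (mode == "capped") scale$C_term_capped else scale$C_term_zwit
  r2 <- c_term * scale$SESA_term +
    sum(scale$coefficients[aa_present] * areas)
  sqrt(r2)
}

#' Write a hydrodiffusivity scale to a plain-text file
#'
#' Versioned tab-separated format: `# key=value` header lines recording the
#' variant, conditions, radius set and SESA parameters, then one `AA<TAB>C`
#' row per amino acid plus `TERM_CAPPED`, `TERM_ZWIT` and `SESA_TERM` rows.
#'
#' @param scale A `ride_hydro_scale`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hydro_scale <- function(scale, path) {
  stopifnot(inherits(scale, "ride_hydro_scale"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# variant=%s", scale$variant),
    sprintf("# temperature=%.10g", scale$temperature),
    sprintf("# viscosity=%.10g", scale$viscosity),
    sprintf("# radii=%s", scale$radius_set_name),
    sprintf("# probe_radius=%.10g", scale$probe_radius),
    sprintf("# n_points=%d", scale$n_points),
    sprintf("# conformation=%s", scale$conformation)
  ), con)
  writeLines(sprintf("%s\t%.10g", names(scale$coefficients),
                     scale$coefficients), con)
  writeLines(c(
    sprintf("TERM_CAPPED\t%.10g", scale$C_term_capped),
    sprintf("TERM_ZWIT\t%.10g", scale$C_term_zwit),
    sprintf("SESA_TERM\t%.10g", scale$SESA_term)
  ), con)
  invisible(path)
}

#' Read a hydrodiffusivity scale file
#'
#' @param path Path to a file written by [write_hydro_scale()].
#' @return A `ride_hydro_scale`.
#' @export
read_hydro_scale <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  toks <- strsplit(body, "\t")
  keys <- vapply(toks, `[`, "", 1)
  vals <- as.numeric(vapply(toks, `[`, "", 2))
  names(vals) <- keys
  coeffs <- vals[AA3]
  if (any(is.na(coeffs))) stop("scale file is missing amino-acid rows")
  scale <- list(
    variant = meta$variant,
    coefficients = coeffs,
    C_term_capped = unname(vals[["TERM_CAPPED"]]),
    C_term_zwit = unname(vals[["TERM_ZWIT"]]),
    SESA_term = unname(vals[["SESA_TERM"]]),
    radius_set_name = meta$radii,
    temperature = as.numeric(meta$temperature),
    viscosity = as.numeric(meta$viscosity),
    probe_radius = as.numeric(meta$probe_radius),
    n_points = as.integer(meta$n_points),
    conformation = meta$conformation
  )
  class(scale) <- "ride_hydro_scale"
  scale
}

#' Load a shipped hydrodiffusivity scale
#'
#' The package ships two scales generated by [build_scale()] from the
#' bundled 310.15 K peptide diffusion table and the package's own fixture
#' structures: `"M"` (capped extended monopeptides) and `"D"` (capped
#' helical decapeptides, which fold secondary-structure propensity into the
#' coefficients and predict systematically faster diffusion).
#'
#' @param variant `"M"` or `"D"`.
#' @return A `ride_hydro_scale`.
#' @export
ride_scale <- function(variant = c("M", "D")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", paste0("hydro_scale_", variant, ".tsv"),
                      package = "ride", mustWork = TRUE)
  read_hydro_scale(path)
}
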