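# Loaders for the shipped simulation reference data.

#' Peptide diffusion reference table at 310.15 K
#'
#' Simulation-derived infinitely dilute diffusion coefficients (1e-5 cm^2/s)
#' and finite-size correction parameters alpha for the ACE/NME-capped mono-
#' and decapeptides of the 20 standard amino acids in TIP3P water at
#' 310.15 K (viscosity 0.275 mPa s). These are shipped inputs -- the
#' molecular-dynamics numbers behind the hydrodiffusivity scales -- and are
#' never recomputed by the package.
#'
#' @return data.frame with columns `aa`, `D0_mono`, `D0_mono_err`,
#'   `alpha_mono`, `alpha_mono_err`, `D0_deca`, `D0_deca_err`, `alpha_deca`,
#'   `alpha_deca_err`.
#' @export
peptide_diffusion_table <- function() {
  path <- system.file("extdata", "peptide_diffusion_310K.tsv",
                      package = "ride", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Reference diffusion estimates for scale building
#'
#' Wraps the shipped 310.15 K peptide diffusion table into the named list of
#' diffusion estimates that [build_scale()] consumes, at the table's
#' conditions (310.15 K, TIP3P viscosity 0.275 mPa s).
#'
#' @param variant `"M"` for the monopeptide column, `"D"` for decapeptides.
#' @return Named list of `ride_diffusion` over the 20 3-letter codes.
#' @export
reference_diffusion_estimates <- function(variant = c("M", "D")) {
  variant <- match.arg(variant)
  tab <- peptide_diffusion_table()
  col <- if (variant == "M") "D0_mono" else "D0_deca"
  err <- if (variant == "M") "D0_mono_err" else "D0_deca_err"
  out <- lapply(seq_len(nrow(tab)), function(i) {
    diffusion_estimate(tab[[col]][i], temperature = 310.15,
                       viscosity = ETA_TIP3P_310,
                       uncertainty = tab[[err]][i], kind = "D_0")
  })
  stats::setNames(out, tab$aa)
}

#' Reference NMA diffusion estimate
#'
#' The simulation infinitely dilute diffusion coefficient of
#' N-methylacetamide, 3.32e-5 cm^2/s at 310.15 K / 0.275 mPa s, the
#' subtraction reference of the hydrodiffusivity-scale derivation.
#'
#' @return A `ride_diffusion`.
#' @export
nma_diffusion <- function() {
  diffusion_estimate(3.32, temperature = 310.15, viscosity = ETA_TIP3P_310,
                     uncertainty = 0.09, kind = "D_0")
}
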