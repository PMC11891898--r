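# mass_relation: Polson-style D ~ M^(-1/3) baseline with calibration on a
# reference protein and optional temperature/viscosity state corrections.

#' Calibrate a mass-relation prefactor
#'
#' A = D_ref * M_ref^(1/3), so that the relation reproduces the reference
#' protein exactly. The shipped default ([default_mass_calibration()]) is
#' derived from the Arc-repressor variant 1BDT (M = 6.14 kg/mol,
#' D = 0.150e-5 cm^2/s in pure water at 293.15 K), since the original
#' hemoglobin-derived constant is not published; any literature (M, D) pair
#' can be supplied instead.
#'
#' @param M_ref Reference molar mass, kg mol^-1.
#' @param D_ref Reference diffusion coefficient, 1e-5 cm^2 s^-1.
#' @param label Provenance label recorded in the calibration.
#' @return A `ride_mass_cal`: list with `A`, `M_ref`, `D_ref`,
#'   `base_temperature` (293.15 K), `label`.
#' @export
calibrate_mass_relation <- function(M_ref, D_ref, label = "user") {
  if (M_ref <= 0 || D_ref <= 0) stop("M_ref and D_ref must be > 0")
  cal <- list(A = D_ref * M_ref^(1 / 3), M_ref = M_ref, D_ref = D_ref,
              base_temperature = 293.15, label = label)
  class(cal) <- "ride_mass_cal"
  cal
}

#' Default mass-relation calibration
#'
#' @return The 1BDT-derived calibration; see [calibrate_mass_relation()].
#' @export
default_mass_calibration <- function() {
  calibrate_mass_relation(6.14, 0.150, label = "1BDT")
}

#' Predict a diffusion coefficient from molar mass
#'
#' D = A / M^(1/3): the cube-root mass relation linking molar mass to
#' diffusivity through molecular volume. Refers to pure water at 293.15 K
#' unless corrected with [correct_to_state()].
#'
#' @param M Molar mass, kg mol^-1 (vectorized).
#' @param cal A `ride_mass_cal` (default [default_mass_calibration()]).
#' @return Diffusion coefficient(s), 1e-5 cm^2 s^-1.
#' @export
predict_D_mass <- function(M, cal = default_mass_calibration()) {
  stopifnot(inherits(cal, "ride_mass_cal"))
  if (any(M <= 0)) stop("M must be > 0")
  cal$A / M^(1 / 3)
}

#' Correct a 293.15 K mass-relation prediction to another state
#'
#' Applies the literal ratio composition D = D_base * T_ratio / eta_ratio
#' with T_ratio = T / 293.15 and eta_ratio = eta_target / eta_exp_293 (the
#' target-state solvent viscosity over the experimental water viscosity at
#' 293.15 K). The ratios used are recorded as attributes; note that which
#' experimental viscosity enters eta_ratio is a genuine ambiguity of this
#' correction, so downstream comparisons against state-corrected literature
#' values should treat it as indicative rather than exact.
#'
#' @param D_base Prediction at 293.15 K in water, 1e-5 cm^2 s^-1.
#' @param temperature Target temperature, K.
#' @param eta_target Target-state viscosity, mPa s.
#' @param eta_exp_293 Experimental water viscosity at 293.15 K, mPa s
#'   (default 1.002).
#' @return Corrected coefficient with attributes `T_ratio` and `eta_ratio`.
#' @export
correct_to_state <- function(D_base, temperature, eta_target,
                             eta_exp_293 = 1.002) {
  if (D_base <= 0 || temperature <= 0 || eta_target <= 0 || eta_exp_293 <= 0) {
    stop("all inputs must be > 0")
  }
  t_ratio <- temperature / 293.15
  eta_ratio <- eta_target / eta_exp_293
  out <- D_base * t_ratio / eta_ratio
  attr(out, "T_ratio") <- t_ratio
  attr(out, "eta_ratio") <- eta_ratio
  out
}
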