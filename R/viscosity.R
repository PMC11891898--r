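# viscosity: solvent viscosity models -- temperature lookup for TIP3P and
# experimental water, NaCl concentration adjustment, simulation-to-
# experiment rescaling, and the periodic-perturbation viscosity estimator.

#' TIP3P viscosity at 310.15 K
#'
#' The independently computed simulation viscosity used alongside the
#' 310.15 K peptide diffusion table (not a node of the shipped
#' temperature table).
#'
#' @export
ETA_TIP3P_310 <- 0.275

#' Load a shipped water viscosity table
#'
#' Shear viscosity of water versus temperature: periodic-perturbation
#' simulation values for the TIP3P model and the experimental liquid,
#' 273.15-323.15 K in 5 K steps. These are shipped input data, not
#' recomputed.
#'
#' @param label `"TIP3P"` or `"experimental"`.
#' @return A `ride_viscosity_table`: list with `label` and `points`
#'   (data.frame `T_K`, `eta`).
#' @export
viscosity_table <- function(label = c("TIP3P", "experimental")) {
  label <- match.arg(label)
  path <- system.file("extdata", "water_viscosity.tsv", package = "ride",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  eta <- if (label == "TIP3P") tab$tip3p else tab$expt
  stopifnot(all(diff(tab$T_K) > 0), all(eta > 0))
  out <- list(label = label, points = data.frame(T_K = tab$T_K, eta = eta))
  class(out) <- "ride_viscosity_table"
  out
}

#' Interpolate viscosity at a temperature
#'
#' Piecewise-linear interpolation between table nodes (exact at nodes).
#' Temperatures up to 2.5 K outside the table range are linearly
#' extrapolated with a warning; farther out is an error.
#'
#' @param table A `ride_viscosity_table`.
#' @param temperature K.
#' @return Viscosity in mPa s.
#' @export
eta_at <- function(table, temperature) {
  stopifnot(inherits(table, "ride_viscosity_table"),
            is.numeric(temperature), length(temperature) == 1)
  Tk <- table$points$T_K
  eta <- table$points$eta
  lo <- min(Tk); hi <- max(Tk)
  if (temperature < lo - 2.5 || temperature > hi + 2.5) {
    stop(sprintf("temperature %.2f K is outside the %s table range [%g, %g] K",
                 temperature, table$label, lo, hi))
  }
  if (temperature < lo || temperature > hi) {
    warning(sprintf("extrapolating %s viscosity %.2f K beyond table range",
                    table$label, temperature))
    i <- if (temperature < lo) 1:2 else (length(Tk) - 1):length(Tk)
    slope <- (eta[i[2]] - eta[i[1]]) / (Tk[i[2]] - Tk[i[1]])
    return(eta[i[1]] + slope * (temperature - Tk[i[1]]))
  }
  stats::approx(Tk, eta, xout = temperature)$y
}

#' NaCl relative-viscosity model
#'
#' Linear law eta(c)/eta(0) = 1 + slope * c for aqueous NaCl. The default
#' slope (0.095 per mol/L) is a straight-line fit to the experimental
#' relative viscosity of NaCl solutions at 293.15 K over 0-1 M (relative
#' viscosity approximately 1.047 at 0.5 M and 1.097 at 1.0 M); the
#' simulated trend follows the experimental one over the same range, so a
#' single experimental slope serves both. Valid to `limit` mol/L.
#'
#' @param slope Relative-viscosity slope, (mol/L)^-1.
#' @param limit Nominal validity limit, mol/L (default 1.0).
#' @return A `ride_salt_model`.
#' @export
salt_model <- function(slope = 0.095, limit = 1.0) {
  stopifnot(slope >= 0, limit > 0)
  m <- list(slope = slope, limit = limit)
  class(m) <- "ride_salt_model"
  m
}

#' Adjust a viscosity for NaCl concentration
#'
#' @param eta0 Salt-free viscosity, mPa s.
#' @param c NaCl molarity, mol/L (>= 0).
#' @param model A `ride_salt_model`, default [salt_model()].
#' @return Adjusted viscosity, mPa s; warns beyond the model's validity limit.
#' @export
salt_adjusted_eta <- function(eta0, c, model = salt_model()) {
  stopifnot(inherits(model, "ride_salt_model"), eta0 > 0)
  if (c < 0) stop("salt concentration must be >= 0")
  if (c > model$limit) {
    warning(sprintf("salt concentration %.3g M exceeds the model validity limit %.3g M",
                    c, model$limit))
  }
  eta0 * (1 + model$slope * c)
}

#' Rescale a simulation diffusion coefficient to experimental viscosity
#'
#' D_eta = D * eta_sim / eta_exp: multiplies a simulation-frame diffusion
#' coefficient by the simulation-to-experiment viscosity ratio so it can be
#' compared with measurements in real water.
#'
#' @param d A `ride_diffusion`.
#' @param eta_sim Simulation viscosity, mPa s.
#' @param eta_exp Experimental viscosity, mPa s.
#' @return A `ride_diffusion` of kind `"D_eta"` carrying `eta_sim`/`eta_exp`
#'   in its `rescaling` field.
#' @export
rescale_to_experiment <- function(d, eta_sim, eta_exp) {
  stopifnot(inherits(d, "ride_diffusion"))
  if (eta_sim <= 0 || eta_exp <= 0) stop("viscosities must be > 0")
  out <- diffusion_estimate(d$value * eta_sim / eta_exp,
                            temperature = d$temperature,
                            viscosity = eta_exp,
                            uncertainty = if (is.na(d$uncertainty)) NA_real_
                                          else d$uncertainty * eta_sim / eta_exp,
                            kind = "D_eta")
  out$rescaling <- c(eta_sim = eta_sim, eta_exp = eta_exp)
  out
}

#' Viscosity from a periodic-perturbation velocity profile
#'
#' In the periodic perturbation method a spatially periodic acceleration
#' a_x(z) = A cos(2 pi z / L_z) drives a steady-state velocity response
#' v_x(z) = V cos(2 pi z / L_z); the Navier-Stokes balance gives
#' eta = A rho / (V k^2) with k = 2 pi / L_z. The amplitude V is obtained by
#' least-squares projection onto the cos/sin pair at wavenumber k, which
#' makes the estimate invariant to a constant drift velocity.
#'
#' @param profile List with `z` (positions, nm, >= 8 bins spanning one
#'   period), `v_x` (velocity samples, nm/ps), `A` (acceleration amplitude,
#'   nm/ps^2), `rho` (mass density, kg/m^3), `L_z` (box height, nm).
#' @return Viscosity in mPa s.
#' @export
viscosity_from_profile <- function(profile) {
  p <- profile
  stopifnot(all(c("z", "v_x", "A", "rho", "L_z") %in% names(p)))
  if (length(p$z) < 8) stop("need at least 8 z-bins spanning one period")
  if (p$A <= 0 || p$rho <= 0 || p$L_z <= 0) {
    stop("A, rho and L_z must all be > 0")
  }
  k <- 2 * pi / p$L_z
  fit <- stats::lm(p$v_x ~ cos(k * p$z) + sin(k * p$z))
  vc <- stats::coef(fit)[[2]]
  vs <- stats::coef(fit)[[3]]
  V <- vc  # generating phase is cosine; sin component is noise
  if (!is.finite(V) || V <= 0) {
    stop("fitted velocity amplitude is not positive; profile not usable ",
         sprintf("(cos amplitude %.3g, sin amplitude %.3g)", vc, vs))
  }
  # A[nm/ps^2] rho[kg/m^3] / (V[nm/ps] k^2[1/nm^2]) = 1e-6 Pa s = 1e-3 mPa s
  1e-3 * p$A * p$rho / (V * k^2)
}
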