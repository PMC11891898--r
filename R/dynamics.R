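# dynamics: trajectory-based diffusion -- MSD with multiple time origins,
# window fitting to D_app, the cubic-cell finite-size relation, 1/L
# extrapolation to D_0, single-box correction, and the Ewald computation of
# the simple-cubic lattice self term.

# finite-size hydrodynamic correction k_B T xi / (6 pi eta L), in
# 1e-5 cm^2/s, for T in K, eta in mPa s, L in nm
fs_correction <- function(temperature, viscosity, L, xi = XI_EW) {
  k <- ride_constants
  k$k_B * temperature * xi /
    (6 * pi * viscosity * k$eta_unit * L * k$length_unit) / k$D_unit
}

#' Mean-square displacement of a trajectory
#'
#' MSD(tau) = < |r(t + tau) - r(t)|^2 > averaged over all time origins t
#' (the desk-scale analogue of averaging independent single-particle
#' traces), for displacements taken across the first `dims` coordinates (or
#' an explicit axis subset).
#'
#' @param traj A `ride_trajectory` (uniformly spaced, unwrapped positions).
#' @param dims Number of dimensions, 1, 2 or 3.
#' @param max_lag Largest lag, ps; must be shorter than the trajectory.
#' @param axes Optional explicit coordinate columns (overrides `dims`).
#' @return A `ride_msd`: list with `lags` (ps), `msd` (nm^2), `n_origins`,
#'   `dims`.
#' @export
compute_msd <- function(traj, dims = 3, max_lag = NULL, axes = NULL) {
  stopifnot(inherits(traj, "ride_trajectory"))
  if (!dims %in% 1:3) stop("dims must be 1, 2 or 3")
  if (is.null(axes)) axes <- seq_len(dims) else dims <- length(axes)
  tms <- traj$times
  n <- length(tms)
  if (n < 2) stop("trajectory needs at least 2 frames")
  dt <- diff(tms)
  if (max(abs(dt - dt[1])) > 1e-9) stop("trajectory spacing is not uniform")
  dt <- dt[1]
  if (is.null(max_lag)) max_lag <- (n - 1) * dt / 2
  if (max_lag >= (n - 1) * dt + 1e-12) {
    stop("max_lag must be shorter than the trajectory duration")
  }
  n_lag <- floor(max_lag / dt)
  pos <- traj$positions[, axes, drop = FALSE]
  msd <- numeric(n_lag + 1)
  n_origins <- integer(n_lag + 1)
  n_origins[1] <- n
  for (l in seq_len(n_lag)) {
    d <- pos[(1 + l):n, , drop = FALSE] - pos[1:(n - l), , drop = FALSE]
    msd[l + 1] <- mean(rowSums(d * d))
    n_origins[l + 1] <- n - l
  }
  out <- list(lags = (0:n_lag) * dt, msd = msd, n_origins = n_origins,
              dims = dims)
  class(out) <- "ride_msd"
  out
}

#' Fit an apparent diffusion coefficient from an MSD window
#'
#' Least-squares slope of MSD versus lag over the window; the diffusion
#' coefficient is slope / (2 d) for d dimensions (one-sixth of the slope in
#' 3-D). The slope standard error is propagated to the estimate.
#'
#' @param msd A `ride_msd`.
#' @param window Length-2 numeric, fit window in ps (default 30-500 ps, the
#'   small-solute window; use 30-3000 ps for proteins).
#' @param temperature,viscosity Optional state metadata for the estimate.
#' @return A `ride_diffusion` of kind `"D_app"` in 1e-5 cm^2 s^-1.
#' @export
fit_dapp <- function(msd, window = c(30, 500),
                     temperature = NA_real_, viscosity = NA_real_) {
  stopifnot(inherits(msd, "ride_msd"), length(window) == 2)
  sel <- msd$lags >= window[1] & msd$lags <= window[2]
  if (sum(sel) < 3) {
    stop("fewer than 3 MSD points in the fit window [",
         window[1], ", ", window[2], "] ps")
  }
  fit <- stats::lm(msd$msd[sel] ~ msd$lags[sel])
  slope <- stats::coef(fit)[[2]]                  # nm^2 / ps
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  if (slope <= 0) stop("non-positive MSD slope in the fit window")
  conv <- 1e3  # nm^2/ps -> 1e-5 cm^2/s
  diffusion_estimate(slope / (2 * msd$dims) * conv,
                     temperature = temperature, viscosity = viscosity,
                     uncertainty = se / (2 * msd$dims) * conv,
                     kind = "D_app")
}

#' Apparent diffusion coefficient in a finite cubic cell
#'
#' The L-dependent relation D_app = D_0 - alpha k_B T xi_EW / (6 pi eta L)
#' for a solute in a cubic periodic cell of edge L.
#'
#' @param D0 Infinite-dilution coefficient, 1e-5 cm^2 s^-1.
#' @param L Box edge, nm.
#' @param temperature K.
#' @param viscosity mPa s.
#' @param alpha Empirical correction factor (1 for an ideal point solute).
#' @param xi Lattice self term (default the cached [XI_EW]).
#' @return D_app in 1e-5 cm^2 s^-1.
#' @export
finite_size_D <- function(D0, L, temperature, viscosity, alpha, xi = XI_EW) {
  if (D0 <= 0 || L <= 0 || temperature <= 0 || viscosity <= 0) {
    stop("D0, L, temperature and viscosity must all be > 0")
  }
  d <- D0 - alpha * fs_correction(temperature, viscosity, L, xi)
  if (d <= 0) {
    stop("finite-size correction exceeds D0 (unphysical regime at L = ",
         L, " nm)")
  }
  d
}

#' Extrapolate a finite-size series to infinite dilution
#'
#' Linear regression of D_app on 1/L: the intercept is D_0 and the slope
#' gives alpha = -slope 6 pi eta / (k_B T xi_EW). When per-entry
#' uncertainties are available they are used as known standard deviations in
#' an inverse-variance weighted fit (parameter errors from the weight
#' matrix); otherwise ordinary least squares with residual-based errors.
#'
#' @param series A `ride_fs_series`.
#' @param xi Lattice self term (default [XI_EW]).
#' @return List with `D0`, `alpha`, `D0_se`, `alpha_se`.
#' @export
extrapolate_D0 <- function(series, xi = XI_EW) {
  stopifnot(inherits(series, "ride_fs_series"))
  e <- series$entries
  if (nrow(e) < 2 || length(unique(e$L)) < 2) {
    stop("need at least 2 distinct box lengths to extrapolate")
  }
  x <- 1 / e$L
  X <- cbind(1, x)
  known_err <- all(is.finite(e$err)) && all(e$err > 0)
  if (known_err) {
    w <- 1 / e$err^2
    XtWX <- crossprod(X * sqrt(w))
    cov <- solve(XtWX)
    beta <- cov %*% crossprod(X * w, e$Dapp)
    se <- sqrt(diag(cov))
  } else {
    fit <- stats::lm(e$Dapp ~ x)
    beta <- stats::coef(fit)
    se <- suppressWarnings(summary(fit))$coefficients[, 2]
  }
  D0 <- beta[[1]]
  slope <- beta[[2]]
  if (D0 <= 0) stop("extrapolated D0 is not positive")
  corr1 <- fs_correction(series$temperature, series$viscosity, 1, xi)
  alpha <- -slope / corr1
  list(D0 = D0, alpha = alpha,
       D0_se = se[[1]], alpha_se = se[[2]] / corr1)
}

#' Single-box finite-size correction
#'
#' Corrects an apparent diffusion coefficient from one cubic cell to
#' infinite dilution: D_0 = D_app + alpha k_B T xi_EW / (6 pi eta L). The
#' factor alpha must be supplied explicitly -- it is solute dependent and is
#' never guessed.
#'
#' @param d A `ride_diffusion` of kind `"D_app"` with temperature and
#'   viscosity set.
#' @param L Box edge, nm.
#' @param alpha Correction factor (> 0), e.g. the 0.86 decapeptide average.
#' @param xi Lattice self term (default [XI_EW]).
#' @return A `ride_diffusion` of kind `"D_0"`.
#' @export
yeh_hummer_correct <- function(d, L, alpha, xi = XI_EW) {
  stopifnot(inherits(d, "ride_diffusion"))
  if (L <= 0 || alpha <= 0) stop("L and alpha must be > 0")
  if (is.na(d$temperature) || is.na(d$viscosity)) {
    stop("estimate lacks temperature or viscosity metadata")
  }
  diffusion_estimate(
    d$value + alpha * fs_correction(d$temperature, d$viscosity, L, xi),
    temperature = d$temperature, viscosity = d$viscosity,
    uncertainty = d$uncertainty, kind = "D_0")
}

# Ewald evaluation of the simple-cubic self term at one splitting parameter
# kappa (unit lattice): real-space erfc sum + reciprocal sum + self and
# background terms. Returns the positive constant.
xi_ewald_once <- function(kappa, nmax, mmax) {
  rng <- -nmax:nmax
  g <- expand.grid(x = rng, y = rng, z = rng)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  r <- r[r > 0]
  real_sum <- sum(erfc_vec(kappa * r) / r)
  rng2 <- -mmax:mmax
  g2 <- expand.grid(x = rng2, y = rng2, z = rng2)
  m2 <- g2$x^2 + g2$y^2 + g2$z^2
  m2 <- m2[m2 > 0]
  recip_sum <- sum(exp(-pi^2 * m2 / kappa^2) / (pi * m2))
  -(real_sum + recip_sum - 2 * kappa / sqrt(pi) - pi / kappa^2)
}

erfc_vec <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Ewald self term of a simple cubic lattice
#'
#' Computes the unitless self-interaction constant of a neutralized simple
#' cubic point lattice by Ewald summation (real-space erfc sum, reciprocal
#' sum, self and background terms), enlarging the cutoffs until the value is
#' stable to `rel_tol` and verifying invariance to the splitting parameter.
#' The converged value is approximately 2.837298.
#'
#' @param rel_tol Relative convergence tolerance (>= 1e-9).
#' @param kappa Ewald splitting parameters used for the cross-check
#'   (length-2 numeric).
#' @return The lattice self term (positive, unitless).
#' @export
compute_xi_ew <- function(rel_tol = 1e-7, kappa = c(1.8, 2.6)) {
  if (rel_tol < 1e-9) stop("rel_tol must be >= 1e-9")
  stopifnot(length(kappa) == 2, all(kappa > 0))
  vals <- vapply(kappa, function(k) {
    prev <- NA_real_
    for (cut in 3:8) {
      v <- xi_ewald_once(k, nmax = cut, mmax = cut)
      if (!is.na(prev) && abs(v - prev) <= rel_tol * abs(v)) return(v)
      prev <- v
    }
    stop("Ewald sum did not converge at rel_tol = ", rel_tol)
  }, numeric(1))
  if (abs(vals[1] - vals[2]) > 2 * rel_tol * abs(vals[1])) {
    stop("Ewald self term depends on the splitting parameter beyond rel_tol; ",
         "not converged")
  }
  mean(vals)
}

#' Repair periodic jumps in a wrapped trajectory
#'
#' Minimum-image unwrapping for an orthorhombic box: any frame-to-frame
#' displacement larger than half the box length along an axis is shifted by
#' the box length. Valid when the true per-step displacement is below L/2.
#'
#' @param traj A `ride_trajectory` with wrapped positions.
#' @param box Length-3 numeric (or scalar) box edge lengths, nm.
#' @return The trajectory with unwrapped positions.
#' @export
unwrap_trajectory <- function(traj, box) {
  stopifnot(inherits(traj, "ride_trajectory"))
  if (length(box) == 1) box <- rep(box, 3)
  pos <- traj$positions
  for (ax in 1:3) {
    d <- diff(pos[, ax])
    jump <- round(d / box[ax])
    pos[, ax] <- pos[, ax] - c(0, cumsum(jump)) * box[ax]
  }
  traj$positions <- pos
  traj
}

#' Read a finite-size series from a TSV file
#'
#' Columns: `L_nm`, `Dapp_1e-5cm2s`, optional `err`.
#'
#' @param path File path.
#' @param temperature K.
#' @param viscosity mPa s.
#' @return A `ride_fs_series`.
#' @export
read_fs_series <- function(path, temperature, viscosity) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("L_nm", "Dapp_1e.5cm2s") %in% names(tab)) &&
      ncol(tab) < 2) {
    stop("finite-size series file needs columns L_nm, Dapp_1e-5cm2s[, err]")
  }
  fs <- list(entries = data.frame(L = tab[[1]], Dapp = tab[[2]],
                                  err = if (ncol(tab) >= 3) tab[[3]]
                                        else NA_real_),
             temperature = temperature, viscosity = viscosity)
  class(fs) <- "ride_fs_series"
  fs
}
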