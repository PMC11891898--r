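# MSD analysis, finite-size extrapolation and the lattice self term

test_that("MSD is exact on stationary and ballistic motion", {
  tr <- gen_brownian_trajectory(0, 100, 3, seed = 1)
  m <- compute_msd(tr, 3, max_lag = 60)
  expect_true(all(m$msd == 0))
  expect_equal(m$msd[1], 0)

  # ballistic r = v t with |v| = 0.1 nm/ps: msd = 0.01 t^2
  times <- (0:200) * 2
  v <- c(0.1, 0, 0) / sqrt(1)  # speed along x
  tr2 <- structure(list(times = times,
                        positions = outer(times, c(0.1, 0, 0)),
                        label = "ballistic"), class = "ride_trajectory")
  m2 <- compute_msd(tr2, 3, max_lag = 100)
  expect_equal(m2$msd, 0.01 * m2$lags^2, tolerance = 1e-12)
  expect_error(compute_msd(tr2, 5), "dims")
  expect_error(compute_msd(tr2, 3, max_lag = 1e6), "shorter")
})

test_that("3-D MSD decomposes into the three 1-D axis curves", {
  tr <- gen_brownian_trajectory(1.0, 2000, 3, seed = 11)
  m3 <- compute_msd(tr, 3, max_lag = 300)
  parts <- lapply(1:3, function(ax) compute_msd(tr, axes = ax, max_lag = 300))
  expect_equal(m3$msd, parts[[1]]$msd + parts[[2]]$msd + parts[[3]]$msd,
               tolerance = 1e-12)
})

test_that("Brownian MSD matches 6 D tau within sampling error", {
  D <- 1.0  # nm^2/ns
  n <- 20000; dt <- 3
  tr <- gen_brownian_trajectory(D, n, dt, seed = 5)
  m <- compute_msd(tr, 3, max_lag = 10 * dt * 30)
  lag_idx <- round(seq(3, length(m$lags), length.out = 10))
  for (l in lag_idx) {
    tau <- m$lags[l]
    expected <- 6 * D * 1e-3 * tau
    n_eff <- floor(n / (l - 1))          # non-overlapping segments
    se_rel <- sqrt(2 / (3 * n_eff))      # chi^2_3 relative error
    expect_lt(abs(m$msd[l] / expected - 1), 3 * se_rel)
  }
})

test_that("D_app fitting recovers exact and simulated slopes", {
  lags <- 0:200
  m <- structure(list(lags = lags, msd = 6 * 2.0e-3 * lags,
                      n_origins = rep(1000, length(lags)), dims = 3),
                 class = "ride_msd")
  expect_equal(fit_dapp(m, c(10, 190))$value, 2.0, tolerance = 1e-12)
  # 2-D normalization: msd = 4 D tau
  m2 <- structure(list(lags = lags, msd = 4 * 2.0e-3 * lags,
                       n_origins = rep(1000, length(lags)), dims = 2),
                  class = "ride_msd")
  expect_equal(fit_dapp(m2, c(10, 190))$value, 2.0, tolerance = 1e-12)
  expect_error(fit_dapp(m, c(500, 600)), "fewer than 3")
})

test_that("the finite-size relation has the right limits and inverse", {
  expect_equal(finite_size_D(1.2, 5, 310.15, 0.275, alpha = 0), 1.2)
  d50 <- finite_size_D(1.2, 50, 310.15, 0.275, alpha = 0.86)
  d5000 <- finite_size_D(1.2, 5000, 310.15, 0.275, alpha = 0.86)
  expect_lt(d50, d5000)
  expect_equal(d5000, 1.2, tolerance = 1e-3)
  expect_error(finite_size_D(0.05, 3, 310.15, 0.275, alpha = 1), "unphysical")

  # yeh_hummer_correct is the exact inverse
  dapp <- finite_size_D(1.2, 5, 310.15, 0.275, alpha = 0.86)
  est <- diffusion_estimate(dapp, 310.15, 0.275, kind = "D_app")
  expect_equal(yeh_hummer_correct(est, 5, 0.86)$value, 1.2, tolerance = 1e-12)
  # monotone in alpha; correction halves when L doubles
  c1 <- yeh_hummer_correct(est, 5, 1.0)$value - dapp
  c086 <- yeh_hummer_correct(est, 5, 0.86)$value - dapp
  expect_gt(c1, c086)
  c_l10 <- yeh_hummer_correct(est, 10, 0.86)$value - dapp
  expect_equal(c_l10, c086 / 2, tolerance = 1e-12)
})

test_that("extrapolation recovers parameters exactly on noiseless series", {
  fs <- gen_finite_size_series(1.12, 0.86, 310.15, 0.275, c(5, 5.5, 6, 6.5, 7))
  ex <- extrapolate_D0(fs)
  expect_equal(ex$D0, 1.12, tolerance = 1e-12)
  expect_equal(ex$alpha, 0.86, tolerance = 1e-12)
  # constant series: alpha = 0, D0 = mean
  fs0 <- gen_finite_size_series(1.12, 0, 310.15, 0.275, c(5, 6, 7))
  ex0 <- extrapolate_D0(fs0)
  expect_equal(ex0$D0, 1.12, tolerance = 1e-12)
  expect_equal(ex0$alpha, 0, tolerance = 1e-12)
  # too few points
  fs1 <- gen_finite_size_series(1.12, 0.86, 310.15, 0.275, 5)
  expect_error(extrapolate_D0(fs1), "at least 2")
})

test_that("noisy extrapolation stays within two standard errors", {
  fs <- gen_finite_size_series(1.12, 0.86, 310.15, 0.275,
                               c(5, 5.5, 6, 6.5, 7), noise_sd = 0.02,
                               seed = 3)
  ex <- extrapolate_D0(fs)
  expect_lt(abs(ex$D0 - 1.12), 2 * ex$D0_se)
  expect_lt(abs(ex$alpha - 0.86), 2 * ex$alpha_se)
})

test_that("the Ewald lattice self term converges and is splitting-invariant", {
  xi <- compute_xi_ew(1e-7)
  expect_equal(xi, 2.837298, tolerance = 1e-6)
  xi_a <- compute_xi_ew(1e-7, kappa = c(1.5, 2.0))
  xi_b <- compute_xi_ew(1e-7, kappa = c(2.2, 3.0))
  expect_equal(xi_a, xi_b, tolerance = 1e-6)
  expect_error(compute_xi_ew(1e-12), "rel_tol")
})

test_that("a tapered direct lattice sum confirms the Ewald value", {
  # independent real-space oracle: 21^3 neutralized lattice with a smooth
  # spherical-shell taper instead of reciprocal-space summation
  rng <- -10:10
  g <- as.matrix(expand.grid(rng, rng, rng))
  r <- sqrt(rowSums(g^2)); r <- r[r > 0]
  smoother <- function(t) ifelse(t <= 0, 1,
                                 ifelse(t >= 1, 0, 1 - (6 * t^5 - 15 * t^4 + 10 * t^3)))
  R1 <- 4; R2 <- 10.5
  w <- smoother((r - R1) / (R2 - R1))
  bg <- 4 * pi * stats::integrate(function(x)
    smoother((x - R1) / (R2 - R1)) * x, 0, R2, rel.tol = 1e-12)$value
  brute <- -(sum(w / r) - bg)
  expect_equal(brute, compute_xi_ew(1e-7), tolerance = 1e-3)
})

test_that("wrapped trajectories unwrap to the original path", {
  tr <- gen_brownian_trajectory(1.0, 5000, 3, seed = 9)
  box <- 4.0
  wrapped <- tr
  wrapped$positions <- tr$positions - box * floor(tr$positions / box)
  fixed <- unwrap_trajectory(wrapped, box)
  # unwrapping restores displacements up to a global offset
  d0 <- sweep(fixed$positions, 2, fixed$positions[1, ])
  d1 <- sweep(tr$positions, 2, tr$positions[1, ])
  expect_equal(d0, d1, tolerance = 1e-9)
})
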