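test_that("unwrapping handles box crossings under a constant box", {
  # particle drifting +0.3 nm/frame through a 2 nm box, crossing once
  x <- seq(0.5, 3.2, by = 0.3)
  w <- x %% 2
  pos <- array(0.5, dim = c(length(x), 1, 3))
  pos[, 1, 1] <- w
  traj <- wrapped_trajectory(pos, 2, frame_dt = 1)
  u <- unwrap_npt(traj)
  expect_equal(u[, 1, 1], x, tolerance = 1e-12)
  # non-crossing axes untouched
  expect_equal(u[, 1, 2], rep(0.5, length(x)))
})

test_that("unwrapping is the identity for a particle that never crosses", {
  set.seed(31)
  pos <- array(runif(20 * 3 * 3, 0.9, 1.1), dim = c(20, 3, 3))
  traj <- wrapped_trajectory(pos, 2, frame_dt = 1)
  expect_equal(unwrap_npt(traj), pos, tolerance = 1e-12)
})

test_that("unwrapping recovers ground truth under a fluctuating box", {
  sys <- generate_brownian_system(10, 20, 400, 1, 3, box_fluct_rel = 0.05,
                                  seed = 32)
  u <- unwrap_npt(sys$trajectory)
  expect_lt(max(abs(u - sys$truth)), 1e-9)
  # wrap-unwrap consistency: rewrapping reproduces the input exactly
  rewrapped <- wrap_positions(u, sys$trajectory$box)
  expect_equal(rewrapped, sys$trajectory$positions, tolerance = 1e-12)
})

test_that("generator is deterministic and degenerate cases behave", {
  a <- generate_brownian_system(5, 4, 50, 1, 3, 0.01, seed = 9)
  b <- generate_brownian_system(5, 4, 50, 1, 3, 0.01, seed = 9)
  expect_identical(a, b)
  frozen <- generate_brownian_system(0, 4, 50, 1, 3, 0, seed = 9)
  expect_true(all(apply(frozen$trajectory$positions, c(2, 3), sd) == 0))
})

test_that("MSD matches closed forms", {
  # ballistic: x = v t -> MSD = v^2 tau^2
  v <- c(0.11, -0.07, 0.05)
  t <- 0:99
  pos <- array(0, dim = c(100, 1, 3))
  for (a in 1:3) pos[, 1, a] <- v[a] * t
  curve <- msd(pos, 30, frame_dt = 1)
  expect_equal(curve$msd_nm2, sum(v^2) * curve$lag_ps^2, tolerance = 1e-9)
  # frozen particles -> all zeros
  frozen <- msd(array(1, dim = c(50, 2, 3)), 10, 1)
  expect_equal(frozen$msd_nm2, rep(0, 11), tolerance = 1e-12)
  expect_error(msd(pos, 200, 1), "invalid argument")
})

test_that("Brownian MSD slope over 6 recovers D within sampling error", {
  D_true <- 12
  sys <- generate_brownian_system(D_true, 60, 2000, 1, 4, 0, seed = 33)
  curve <- msd(sys$truth, 100, 1)
  fit <- fit_diffusion(curve)
  expect_lt(abs(fit$D - D_true), 3 * fit$se_D)
})

test_that("GLS fit is exact in the noiseless limit with Q = 1", {
  D <- 5
  curve <- structure(
    list(lag_ps = 0:120, msd_nm2 = 6 * D * (0:120) / 1000,
         count = rep(1000L, 121), n_frames = 1000L, n_particles = 10L,
         frame_dt = 1,
         per_particle = matrix(6 * D * (0:120) / 1000, 10, 121,
                               byrow = TRUE)),
    class = "msd_curve")
  fit <- fit_diffusion(curve)
  expect_equal(fit$D, D, tolerance = 1e-9)
  expect_equal(fit$chisq, 0, tolerance = 1e-9)
  expect_equal(fit$Q, 1)
  expect_error(fit_diffusion(curve, t_min = 119), "insufficient data")
})

test_that("diffusion fit is invariant to a constant position offset", {
  sys <- generate_brownian_system(8, 30, 800, 1, 4, 0, seed = 34)
  f1 <- fit_diffusion(msd(sys$truth, 80, 1))
  shifted <- sys$truth + 123.4
  f2 <- fit_diffusion(msd(shifted, 80, 1))
  expect_equal(f2$D, f1$D, tolerance = 1e-8)
  expect_equal(f2$Q, f1$Q, tolerance = 1e-6)
})

test_that("per-seed coverage of the full pipeline is calibrated", {
  n_seed <- 25
  hits <- 0
  for (i in seq_len(n_seed)) {
    sys <- generate_brownian_system(23.65, 40, 1500, 1, 4, 0.003,
                                    seed = 600 + i)
    fit <- fit_diffusion(msd(unwrap_npt(sys$trajectory), 150, 1))
    hits <- hits + (abs(fit$D - 23.65) <= 3 * fit$se_D)
  }
  expect_gte(hits / n_seed, 0.95)
})

test_that("finite-size extrapolation recovers a known straight line", {
  L <- c(2.5, 3.2, 4.1, 5.5)
  D <- 23.648 - 8 / L
  fit <- finite_size_extrapolation(L, D, temperature = 310)
  expect_equal(fit$D_inf, 23.648, tolerance = 1e-9)
  expect_equal(fit$slope, -8, tolerance = 1e-9)
  # reordering points leaves the intercept unchanged
  fit2 <- finite_size_extrapolation(rev(L), rev(D), 310)
  expect_equal(fit2$D_inf, fit$D_inf, tolerance = 1e-12)
  # size-independent D: zero slope, infinite viscosity flag
  flat <- finite_size_extrapolation(L, rep(7, 4), 310)
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expect_true(is.infinite(flat$eta_pa_s))
  expect_error(finite_size_extrapolation(c(3, 3), c(1, 2), 310),
               "singular fit")
})

test_that("viscosity round-trips through the Yeh-Hummer slope", {
  eta <- 3.2e-4  # Pa s, water-like
  L <- c(2.5, 3.5, 5, 8)
  D <- yeh_hummer_prediction(23.648, eta, L, 310)
  fit <- finite_size_extrapolation(L, D, 310)
  expect_equal(fit$eta_pa_s, eta, tolerance = 1e-9)
  expect_equal(fit$D_inf, 23.648, tolerance = 1e-9)
})

test_that("equipartition temperatures separate translation and rotation", {
  m <- tip3p_site_masses
  tr <- sample_water_velocities(4000, 298.15, mode = "translation",
                                seed = 41)
  rep_tr <- rigid_body_temperatures(tr$positions, tr$velocities, m)
  expect_lt(abs(rep_tr$T_trs - 298.15), 3 * 298.15 * sqrt(2 / (3 * 4000)))
  expect_equal(rep_tr$T_rot, 0, tolerance = 1e-9)

  ro <- sample_water_velocities(4000, 298.15, mode = "rotation", seed = 42)
  rep_ro <- rigid_body_temperatures(ro$positions, ro$velocities, m)
  expect_equal(rep_ro$T_trs, 0, tolerance = 1e-9)
  expect_lt(abs(rep_ro$T_rot - 298.15), 4 * 298.15 * sqrt(2 / (3 * 4000)))

  eq <- sample_water_velocities(20000, 298.15, seed = 43)
  rep_eq <- rigid_body_temperatures(eq$positions, eq$velocities, m)
  expect_lt(abs(rep_eq$T_trs - 298.15), 3)
  expect_lt(abs(rep_eq$T_rot - 298.15), 3)

  # collinear sites -> singular inertia
  lin_pos <- array(0, dim = c(5, 3, 3))
  lin_pos[, 2, 1] <- 0.1
  lin_pos[, 3, 1] <- -0.1
  expect_error(rigid_body_temperatures(lin_pos, lin_pos, m),
               "degenerate geometry")
})
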