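test_that("linear ACF: normalization, white noise, and the AR(1) closed form", {
  set.seed(51)
  wn <- cv_series(rnorm(20000), frame_dt = 1)
  a <- autocorrelation(wn, max_lag = 50)
  expect_equal(a$values[1], 1)
  expect_true(all(abs(a$values[-1]) < 3 / sqrt(20000)))

  rho <- 0.8
  x <- ar1_series(2e5, rho, seed = 52)
  a2 <- autocorrelation(cv_series(x, 1), max_lag = 10)
  expect_equal(a2$values[1:8], rho^(0:7), tolerance = 0.03)

  expect_error(autocorrelation(cv_series(rep(1, 100), 1), 10),
               "degenerate series")
  expect_error(autocorrelation(cv_series(rnorm(10), 1, circular = TRUE), 5),
               "type error")
})

test_that("dihedral ACF: constant, uniform and confined-well behaviour", {
  const <- cv_series(rep(42, 500), 1, circular = TRUE)
  a <- vdsb_dihedral_acf(const, 20)
  expect_equal(a$values, rep(1, 21), tolerance = 1e-12)

  set.seed(53)
  unif <- cv_series(runif(20000, -180, 180), 1, circular = TRUE)
  au <- vdsb_dihedral_acf(unif, 20)
  expect_equal(au$values[1], 1)
  expect_true(all(abs(au$values[-1]) < 4 / sqrt(20000)))

  expect_error(vdsb_dihedral_acf(cv_series(rnorm(100), 1), 10), "type error")

  # confined well: ACF decays to ~S_D^2 and slows down with friction
  pot <- dihedral_potential(k = -8, j = 1)
  fast <- generate_dihedral_series(pot, friction = 2, temperature = 310,
                                   dt = 0.01, n_steps = 6e4, seed = 54)[[1]]
  slow <- generate_dihedral_series(pot, friction = 8, temperature = 310,
                                   dt = 0.01, n_steps = 6e4, seed = 55)[[1]]
  s2 <- dihedral_order_parameter(fast)
  af <- vdsb_dihedral_acf(fast, 6)
  as_ <- vdsb_dihedral_acf(slow, 6)
  expect_lt(abs(af$values[length(af$values)] - s2), 0.05)
  # slower friction decays slower at a fixed short lag
  expect_gt(as_$values[30], af$values[30])
})

test_that("dihedral order parameter spans its closed-form limits", {
  expect_equal(dihedral_order_parameter(rep(77, 10)), 1, tolerance = 1e-12)
  expect_equal(dihedral_order_parameter(c(0, 180, 0, 180)), 0,
               tolerance = 1e-12)
  set.seed(56)
  expect_lt(dihedral_order_parameter(runif(50000, -180, 180)), 0.005)
  expect_error(dihedral_order_parameter(numeric(0)), "invalid argument")
})

test_that("integrated ACT: white-noise floor, AR(1) closed form, replica SE", {
  set.seed(57)
  wn <- autocorrelation(cv_series(rnorm(50000), 2), 100)
  est <- integrated_act(wn)
  expect_lt(abs(est$tau_int - 0.5 * 2 / 1000), 0.1 * 2 / 1000)

  rho <- 0.9
  tau_true <- (0.5 + rho / (1 - rho)) / 1000  # ns at frame_dt 1 ps
  a <- autocorrelation(cv_series(ar1_series(1e6, rho, seed = 58), 1), 500)
  est2 <- integrated_act(a)
  expect_lt(abs(est2$tau_int - tau_true) / tau_true, 0.05)

  # SE across replicas shrinks as 1/sqrt(n)
  acfs <- lapply(1:10, function(i) {
    autocorrelation(cv_series(ar1_series(20000, 0.8, seed = 600 + i), 1),
                    200)
  })
  est10 <- integrated_act(acfs)
  expect_equal(est10$n_replicas, 10L)
  expect_equal(est10$se_int, sd(est10$per_replica) / sqrt(10))
  # alternative window rule runs and gives a comparable answer
  estfn <- integrated_act(a, window_rule = "first_negative")
  expect_lt(abs(estfn$tau_int - tau_true) / tau_true, 0.2)
})

test_that("exponential ACT: exact on a pure exponential, errors on bad ranges", {
  tau <- 40  # ps
  acf <- structure(list(lag_ps = 0:200, values = exp(-(0:200) / tau),
                        frame_dt = 1, type = "linear", n = 1000L),
                   class = "series_acf")
  est <- exponential_act(acf)
  expect_equal(est$tau_exp, tau / 1000, tolerance = 1e-9)
  est2 <- exponential_act(acf, fit_range = c(30, 120))
  expect_equal(est2$tau_exp, tau / 1000, tolerance = 1e-9)

  # two-scale decay: tail fit recovers the slow component
  acf2 <- acf
  acf2$values <- 0.5 * exp(-(0:200) / 3) + 0.5 * exp(-(0:200) / 50)
  est3 <- exponential_act(acf2, fit_range = c(60, 180))
  expect_lt(abs(est3$tau_exp - 0.05) / 0.05, 0.05)

  acf3 <- acf
  acf3$values[100:201] <- -0.01
  expect_error(exponential_act(acf3, fit_range = c(50, 150)),
               "invalid range")
})

test_that("block-average SEM matches iid and correlated closed forms", {
  expect_equal(block_sem(rep(3.7, 1000))$sem, 0)
  expect_error(block_sem(rnorm(10)), "insufficient data")

  set.seed(61)
  x <- rnorm(40000, sd = 2.5)
  expect_lt(abs(block_sem(x)$sem / (sd(x) / sqrt(40000)) - 1), 0.2)

  rho <- 0.9
  y <- ar1_series(2e5, rho, seed = 62)
  tau_int <- 0.5 + rho / (1 - rho)
  sem_true <- sd(y) * sqrt(2 * tau_int / 2e5)
  expect_lt(abs(block_sem(y)$sem / sem_true - 1), 0.3)
})

test_that("free-energy profiles follow -kT ln p with masked empty bins", {
  # two equal bins -> zero difference
  x <- c(rep(0.25, 400), rep(0.75, 400))
  fe <- free_energy_profile(x, bin_edges = c(0, 0.5, 1), temperature = 310)
  expect_equal(fe$G, c(0, 0))
  expect_equal(sum(fe$p), 1)

  # probability ratio e -> delta G = kB T (2.578 kJ/mol at 310 K)
  n2 <- 1000
  n1 <- round(exp(1) * n2)
  xe <- c(rep(0.25, n1), rep(0.75, n2))
  fee <- free_energy_profile(xe, c(0, 0.5, 1), 310)
  expect_equal(fee$G[2] - fee$G[1], 0.0083144621 * 310 * log(n1 / n2),
               tolerance = 1e-9)
  expect_equal(fee$G[2], 2.578, tolerance = 0.01)

  # empty bins masked, not zero
  fm <- free_energy_profile(c(rep(0.1, 10), rep(0.9, 5)),
                            bin_edges = seq(0, 1, 0.25), 310)
  expect_true(is.na(fm$G[2]) && is.na(fm$G[3]))
  expect_equal(min(fm$G, na.rm = TRUE), 0)
  expect_error(free_energy_profile(c(5, 6), bin_edges = c(0, 1), 310),
               "empty histogram")
})

test_that("2D free-energy surfaces are consistent with 1D marginals", {
  set.seed(63)
  phi <- runif(20000, -180, 180)
  psi <- 90 * sin(phi * pi / 180) + rnorm(20000, sd = 20)
  ex <- seq(-180, 180, by = 30)
  ey <- seq(-180, 180, by = 30)
  surf <- free_energy_surface(phi, psi, ex, ey, 310)
  keep <- psi > -180 & psi <= 180
  prof <- free_energy_profile(phi[keep], ex, 310)
  expect_equal(rowSums(surf$counts), prof$counts)
  # difference map on shared bins is zero against itself
  expect_true(all(fe_difference(surf, surf) == 0, na.rm = TRUE))
  surf2 <- free_energy_surface(phi, psi, seq(-180, 180, by = 60), ey, 310)
  expect_error(fe_difference(surf, surf2), "shared bins")
})

test_that("pairwise KS statistics agree with stats::ks.test", {
  set.seed(64)
  x <- rnorm(300)
  y <- rnorm(400, mean = 0.3)
  ours <- fastwater:::.ks_stat(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y))
  expect_equal(ours$stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fastwater:::.ks_stat(x, x)$stat, 0)
})

test_that("replica KS comparison separates null from shifted alternatives", {
  set.seed(65)
  make_group <- function(shift) {
    lapply(1:5, function(i) rnorm(800, mean = shift))
  }
  null_cmp <- ks_replica_comparison(make_group(0), make_group(0))
  expect_gte(null_cmp$overlap, 0.8)
  alt_cmp <- ks_replica_comparison(make_group(0), make_group(3))
  expect_lte(alt_cmp$overlap, 0.2)
  expect_gt(median(alt_cmp$between$stat), median(alt_cmp$within_a$stat))
  expect_error(ks_replica_comparison(list(rnorm(10)), make_group(0)),
               "insufficient replicas")
})

test_that("internal-friction fit recovers straight lines and SE coverage", {
  m <- c(0.5, 1.116, 4.5, 9, 18.0154)
  tau <- 0.041 + 0.013 * sqrt(m)
  fit <- internal_friction_fit(m, tau)
  expect_equal(fit$a, 0.041, tolerance = 1e-10)
  expect_equal(fit$b, 0.013, tolerance = 1e-10)
  # flat data
  flat <- internal_friction_fit(m, rep(0.2, 5))
  expect_equal(flat$a, 0.2, tolerance = 1e-10)
  expect_equal(flat$b, 0, tolerance = 1e-10)
  expect_error(internal_friction_fit(c(1, 1), c(1, 2)), "insufficient data")

  # heteroscedastic noise: ~95% coverage at 2 sigma
  set.seed(66)
  se <- c(0.002, 0.001, 0.001, 0.002, 0.004)
  cover_a <- cover_b <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    noisy <- tau + rnorm(5, sd = se)
    f <- internal_friction_fit(m, noisy, se)
    cover_a <- cover_a + (abs(f$a - 0.041) <= 2 * f$se_a)
    cover_b <- cover_b + (abs(f$b - 0.013) <= 2 * f$se_b)
  }
  expect_gt(cover_a / n_rep, 0.88)
  expect_gt(cover_b / n_rep, 0.88)
})

test_that("Langevin dihedral generator samples the Boltzmann distribution", {
  pot <- dihedral_potential(k = -8, j = 1)
  ser <- generate_dihedral_series(pot, friction = 5, temperature = 310,
                                  dt = 0.01, n_steps = 1.2e5, seed = 71)[[1]]
  # thin far beyond tau_int (~60 frames) for an effectively iid sample
  thin <- ser$values[seq(500, length(ser$values), by = 600)]
  dens <- dihedral_stationary_density(pot, 310)
  cdf_fun <- approxfun(dens$theta_deg, dens$cdf, rule = 2)
  ks <- suppressWarnings(stats::ks.test(thin, cdf_fun))
  expect_gt(ks$p.value, 0.01)
  # determinism
  r1 <- generate_dihedral_series(pot, 5, dt = 0.01, n_steps = 100, seed = 3)
  r2 <- generate_dihedral_series(pot, 5, dt = 0.01, n_steps = 100, seed = 3)
  expect_identical(r1, r2)
  # unstable step rejected
  expect_error(generate_dihedral_series(pot, friction = 1, dt = 0.2,
                                        n_steps = 10, seed = 1),
               "integration error")
})

test_that("stationary statistics are mass-invariant while tau scales", {
  pot <- dihedral_potential(k = -8, j = 1)
  get <- function(ms, seed) {
    generate_dihedral_series(pot, friction = 5, mass_scale = ms,
                             temperature = 310, dt = 0.01, n_steps = 8e4,
                             seed = seed, n_replicas = 2)
  }
  heavy <- get(1, 72)
  light <- get(1 / 4, 73)
  thin_h <- unlist(lapply(heavy, function(s)
    s$values[seq(400, length(s$values), by = 500)]))
  thin_l <- unlist(lapply(light, function(s)
    s$values[seq(400, length(s$values), by = 500)]))
  expect_gt(suppressWarnings(stats::ks.test(thin_h, thin_l))$p.value, 0.01)
  # order parameter invariant within statistical error
  expect_lt(abs(dihedral_order_parameter(cv_series(thin_h, 1,
                                                   circular = TRUE)) -
                  dihedral_order_parameter(cv_series(thin_l, 1,
                                                     circular = TRUE))),
            0.05)
  # tau_int halves at quarter mass
  tau_of <- function(series_list) {
    integrated_act(lapply(series_list, function(s)
      vdsb_dihedral_acf(s, 20, normalize = "plateau")))$tau_int
  }
  expect_equal(tau_of(heavy) / tau_of(light), 2, tolerance = 0.15)
})

test_that("friction floor produces a nonzero intercept in tau vs sqrt(mass)", {
  pot <- dihedral_potential(k = -8, j = 1)
  scales <- c(1, 0.25, 0.0625)
  taus <- vapply(seq_along(scales), function(i) {
    ser <- generate_dihedral_series(pot, friction = 4, mass_scale = scales[i],
                                    friction_floor = 2, temperature = 310,
                                    dt = 0.01, n_steps = 8e4,
                                    seed = 80 + i, n_replicas = 2)
    integrated_act(lapply(ser, function(s)
      vdsb_dihedral_acf(s, 20, normalize = "plateau")))$tau_int
  }, numeric(1))
  fit <- internal_friction_fit(scales, taus)  # mass-scale plays the m role
  # gamma_eff = 2 + 4 sqrt(ms): intercept fraction 2/(2+4) of tau at ms = 1
  expect_gt(fit$a, 0)
  expect_equal(fit$a / (fit$a + fit$b), 2 / 6, tolerance = 0.2)
})

test_that("free-energy profiles from independent runs agree within kT", {
  pot <- dihedral_potential(k = -8, j = 1)
  s1 <- generate_dihedral_series(pot, 5, temperature = 310, dt = 0.01,
                                 n_steps = 1e5, seed = 74)[[1]]
  s2 <- generate_dihedral_series(pot, 5, temperature = 310, dt = 0.01,
                                 n_steps = 1e5, seed = 75)[[1]]
  edges <- seq(-180, 180, by = 10)
  f1 <- free_energy_profile(s1, edges, 310)
  f2 <- free_energy_profile(s2, edges, 310)
  # raw frames are correlated (tau_int ~ 60 frames); a bin is well-sampled
  # once it holds >= 10 *independent* visits, i.e. 10 * 2 tau_int frames
  tau_frames <- integrated_act(
    vdsb_dihedral_acf(s1, 20, normalize = "plateau"))$tau_int * 1000 / 0.01
  floor_counts <- 10 * 2 * tau_frames
  well <- which(f1$counts >= floor_counts & f2$counts >= floor_counts)
  expect_gt(length(well), 5)
  kT <- 0.0083144621 * 310
  expect_true(all(abs(f1$G[well] - f2$G[well]) <= kT))
  # sparse edge bins are exactly where larger deviations live
  sparse <- which(f1$counts > 0 & f2$counts > 0 & f1$counts < floor_counts)
  expect_gt(max(abs(f1$G[sparse] - f2$G[sparse])), kT / 2)
})
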