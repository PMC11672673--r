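# Overdamped Langevin dynamics of a dihedral on a periodic multi-well
# potential.
#
# The stationary density exp(-U/kBT) is independent of the friction, so
# mass/friction scaling changes relaxation times (as sqrt(mass)) while
# leaving every equilibrium statistic untouched -- the property that makes
# "fast water" safe. An additive friction floor emulates the residual
# (internal + thermostat) friction that survives as the solvent mass goes
# to zero.

#' Periodic multi-well dihedral potential
#'
#' `U(theta) = sum_j k_j cos(j theta - delta_j)` (kJ/mol, theta in degrees
#' externally, radians internally).
#'
#' @param k Fourier amplitudes (kJ/mol)
#' @param j integer multiplicities (same length as `k`)
#' @param delta phase offsets (degrees; default 0)
#' @return Object of class `dihedral_potential` with `energy(theta_deg)`
#'   and `force(theta_rad)` evaluators.
#' @export
dihedral_potential <- function(k, j = seq_along(k), delta = rep(0, length(k))) {
  stopifnot(length(k) == length(j), length(k) == length(delta),
            all(j == round(j)), all(j >= 1))
  delta_rad <- delta * pi / 180
  structure(
    list(k = k, j = as.integer(j), delta = delta,
         energy = function(theta_deg) {
           th <- theta_deg * pi / 180
           vapply(th, function(t) sum(k * cos(j * t - delta_rad)),
                  numeric(1))
         },
         # -dU/dtheta in kJ/mol/rad, vectorized over theta (radians)
         force = function(theta_rad) {
           f <- 0
           for (i in seq_along(k)) {
             f <- f + k[i] * j[i] * sin(j[i] * theta_rad - delta_rad[i])
           }
           f
         },
         curvature_bound = sum(abs(k) * j^2)),
    class = "dihedral_potential"
  )
}

#' Stationary density of a dihedral potential
#'
#' Boltzmann density `exp(-U/kB T)` on (-180, 180], normalized numerically;
#' the analytic oracle for the generator's equilibrium distribution.
#'
#' @param potential a [dihedral_potential()]
#' @param temperature temperature (K)
#' @param n_grid grid resolution
#' @return Data.frame with `theta_deg`, `density` (per degree), `cdf`.
#' @export
dihedral_stationary_density <- function(potential, temperature,
                                        n_grid = 3601L) {
  grid <- seq(-180, 180, length.out = n_grid)
  u <- potential$energy(grid)
  dens <- exp(-(u - min(u)) / (.kB * temperature))
  h <- diff(grid[1:2])
  Z <- sum((dens[-1] + dens[-n_grid]) / 2) * h
  dens <- dens / Z
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2) * h)
  data.frame(theta_deg = grid, density = dens, cdf = cdf / cdf[n_grid])
}

#' Simulate overdamped Langevin dihedral dynamics
#'
#' Euler--Maruyama integration of
#' `dtheta = -U'(theta)/gamma_eff dt + sqrt(2 kB T dt / gamma_eff) xi`,
#' with the effective friction
#' `gamma_eff = friction_floor + friction * sqrt(mass_scale)`: solvent
#' friction scales with the square root of the solvent mass-scale factor
#' (so relaxation times scale as sqrt(mass)) while the stationary density
#' `exp(-U/kB T)` is unchanged. Stability requires
#' `dt < 0.5 gamma_eff / max|U''|`; larger steps raise an error.
#'
#' @param potential a [dihedral_potential()]
#' @param friction solvent friction coefficient at mass_scale 1
#'   (kJ mol^-1 ps rad^-2), > 0
#' @param mass_scale solvent mass-scale factor f^2 (1 = reference mass)
#' @param temperature temperature (K)
#' @param dt integration step (ps)
#' @param n_steps number of integration steps
#' @param seed integer seed
#' @param n_replicas independent replicas integrated in parallel
#' @param stride record every `stride`-th step (frame_dt = dt * stride)
#' @param friction_floor additive friction floor (internal + thermostat
#'   friction; default 0)
#' @param theta0_deg starting angle(s), degrees; default: drawn from the
#'   stationary density
#' @return List of [cv_series()] (circular, degrees), one per replica.
#' @export
generate_dihedral_series <- function(potential, friction, mass_scale = 1,
                                     temperature = 310, dt = 0.01,
                                     n_steps = 1e5L, seed = 1,
                                     n_replicas = 1L, stride = 1L,
                                     friction_floor = 0,
                                     theta0_deg = NULL) {
  stopifnot(inherits(potential, "dihedral_potential"), friction > 0,
            mass_scale > 0, temperature > 0, dt > 0, n_steps >= 1,
            n_replicas >= 1, stride >= 1, friction_floor >= 0)
  gamma_eff <- friction_floor + friction * sqrt(mass_scale)
  kT <- .kB * temperature
  kappa <- potential$curvature_bound
  if (kappa > 0 && dt > 0.5 * gamma_eff / kappa) {
    stop(sprintf(
      "integration error: dt = %g ps exceeds the stability bound %g ps
(0.5 * gamma_eff / max|U''|); reduce dt or raise the friction", dt,
      0.5 * gamma_eff / kappa), call. = FALSE)
  }
  set.seed(seed)
  if (is.null(theta0_deg)) {
    sd_ <- dihedral_stationary_density(potential, temperature)
    u <- stats::runif(n_replicas)
    theta <- stats::approx(sd_$cdf, sd_$theta_deg, xout = u,
                           ties = "ordered")$y * pi / 180
  } else {
    theta <- rep(theta0_deg * pi / 180, length.out = n_replicas)
  }
  noise_sd <- sqrt(2 * kT * dt / gamma_eff)
  drift_fac <- dt / gamma_eff
  n_frames <- floor(n_steps / stride)
  out <- matrix(NA_real_, n_frames, n_replicas)
  frame <- 0L
  # pre-draw noise in chunks to keep memory bounded for long runs
  chunk <- 50000L
  step_in_chunk <- chunk
  noise <- NULL
  for (s in seq_len(n_steps)) {
    if (step_in_chunk == chunk) {
      noise <- matrix(stats::rnorm(min(chunk, n_steps - s + 1L) * n_replicas,
                                   sd = noise_sd),
                      ncol = n_replicas)
      step_in_chunk <- 0L
    }
    step_in_chunk <- step_in_chunk + 1L
    theta <- theta + drift_fac * potential$force(theta) +
      noise[step_in_chunk, ]
    if (s %% stride == 0L) {
      frame <- frame + 1L
      out[frame, ] <- theta
    }
  }
  lapply(seq_len(n_replicas), function(r) {
    cv_series(out[, r] * 180 / pi, frame_dt = dt * stride, circular = TRUE,
              replica_id = r)
  })
}
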