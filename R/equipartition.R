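# Rigid-body kinetic temperature diagnostics for 3-site molecules.
#
# Decomposes site velocities into centre-of-mass translation and rigid-body
# rotation (angular velocity from the inertia tensor about the COM) and
# reports the kinetic temperatures of the two subsets. Divergence between
# T_trs and T_rot diagnoses integrator/thermostat artefacts that grow with
# the effective time step.

#' Rigid 3-site water geometry
#'
#' Site coordinates (nm) of a rigid 3-site water: O at the origin, O-H bond
#' length 0.09572 nm, H-O-H angle 104.52 degrees, in the molecular plane.
#'
#' @return 3 x 3 matrix (rows O, H1, H2; columns x, y, z), nm.
#' @export
water_site_geometry <- function() {
  r_oh <- 0.09572
  half <- 104.52 / 2 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = c(r_oh * sin(half),  r_oh * cos(half), 0),
        H2 = c(-r_oh * sin(half), r_oh * cos(half), 0))
}

# vectorized 3x3 inverse applied to vectors: solves I w = L per molecule.
# Ixx.. are length-n vectors of tensor components, L is n x 3.
.solve_inertia <- function(Ixx, Iyy, Izz, Ixy, Ixz, Iyz, L) {
  det <- Ixx * (Iyy * Izz - Iyz^2) - Ixy * (Ixy * Izz - Iyz * Ixz) +
    Ixz * (Ixy * Iyz - Iyy * Ixz)
  scale <- (abs(Ixx) + abs(Iyy) + abs(Izz))^3
  if (any(abs(det) < 1e-12 * pmax(scale, .Machine$double.xmin))) {
    stop("degenerate geometry: singular inertia tensor (collinear sites)",
         call. = FALSE)
  }
  # adjugate rows
  a11 <- Iyy * Izz - Iyz^2
  a12 <- Ixz * Iyz - Ixy * Izz
  a13 <- Ixy * Iyz - Ixz * Iyy
  a22 <- Ixx * Izz - Ixz^2
  a23 <- Ixy * Ixz - Ixx * Iyz
  a33 <- Ixx * Iyy - Ixy^2
  cbind(a11 * L[, 1] + a12 * L[, 2] + a13 * L[, 3],
        a12 * L[, 1] + a22 * L[, 2] + a23 * L[, 3],
        a13 * L[, 1] + a23 * L[, 2] + a33 * L[, 3]) / det
}

#' Translational and rotational kinetic temperatures
#'
#' For each 3-site molecule the centre-of-mass velocity gives the
#' translational kinetic energy and the residual site velocities are
#' projected onto rigid-body rotation (angular velocity `w = I^-1 L` with
#' `L` the angular momentum about the COM), giving the rotational kinetic
#' energy `w . L / 2` over 3 rotational degrees of freedom. Temperatures
#' are `T = 2 KE_total / (3 N kB)` for each subset.
#'
#' @param site_positions array (n_molecules, 3 sites, 3 axes), nm
#' @param site_velocities array of the same shape, nm/ps
#' @param site_masses length-3 site masses (g/mol), site order matching the
#'   arrays
#' @return Object of class `temperature_report`: list with `T_trs`, `T_rot`
#'   (K) and `n_molecules`.
#' @export
rigid_body_temperatures <- function(site_positions, site_velocities,
                                    site_masses) {
  stopifnot(is.array(site_positions), length(dim(site_positions)) == 3L,
            all(dim(site_positions) == dim(site_velocities)),
            dim(site_positions)[2] == 3L, dim(site_positions)[3] == 3L,
            length(site_masses) == 3L, all(site_masses > 0))
  n <- dim(site_positions)[1]
  m <- site_masses
  M <- sum(m)

  v_com <- (m[1] * site_velocities[, 1, ] + m[2] * site_velocities[, 2, ] +
              m[3] * site_velocities[, 3, ]) / M
  if (n == 1L) v_com <- matrix(v_com, 1, 3)
  T_trs <- sum(M * rowSums(v_com^2)) / (3 * n * .kB)

  r_com <- (m[1] * site_positions[, 1, ] + m[2] * site_positions[, 2, ] +
              m[3] * site_positions[, 3, ]) / M
  if (n == 1L) r_com <- matrix(r_com, 1, 3)

  Ixx <- Iyy <- Izz <- Ixy <- Ixz <- Iyz <- numeric(n)
  Lang <- matrix(0, n, 3)
  for (s in 1:3) {
    r <- matrix(site_positions[, s, ], n, 3) - r_com
    v <- matrix(site_velocities[, s, ], n, 3) - v_com
    Ixx <- Ixx + m[s] * (r[, 2]^2 + r[, 3]^2)
    Iyy <- Iyy + m[s] * (r[, 1]^2 + r[, 3]^2)
    Izz <- Izz + m[s] * (r[, 1]^2 + r[, 2]^2)
    Ixy <- Ixy - m[s] * r[, 1] * r[, 2]
    Ixz <- Ixz - m[s] * r[, 1] * r[, 3]
    Iyz <- Iyz - m[s] * r[, 2] * r[, 3]
    Lang <- Lang + m[s] * cbind(r[, 2] * v[, 3] - r[, 3] * v[, 2],
                                r[, 3] * v[, 1] - r[, 1] * v[, 3],
                                r[, 1] * v[, 2] - r[, 2] * v[, 1])
  }
  omega <- .solve_inertia(Ixx, Iyy, Izz, Ixy, Ixz, Iyz, Lang)
  T_rot <- sum(rowSums(omega * Lang)) / (3 * n * .kB)

  structure(list(T_trs = T_trs, T_rot = T_rot, n_molecules = n),
            class = "temperature_report")
}

#' @export
print.temperature_report <- function(x, ...) {
  cat(sprintf("Equipartition: T_trs = %.3f K, T_rot = %.3f K (%d molecules)\n",
              x$T_trs, x$T_rot, x$n_molecules))
  invisible(x)
}

# random rotation matrices via normalized quaternions; q is n x 4 std normal
.random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  list(
    r11 = 1 - 2 * (y^2 + z^2), r12 = 2 * (x * y - w * z),
    r13 = 2 * (x * z + w * y),
    r21 = 2 * (x * y + w * z), r22 = 1 - 2 * (x^2 + z^2),
    r23 = 2 * (y * z - w * x),
    r31 = 2 * (x * z - w * y), r32 = 2 * (y * z + w * x),
    r33 = 1 - 2 * (x^2 + y^2)
  )
}

.apply_rotations <- function(R, vec) {
  cbind(R$r11 * vec[, 1] + R$r12 * vec[, 2] + R$r13 * vec[, 3],
        R$r21 * vec[, 1] + R$r22 * vec[, 2] + R$r23 * vec[, 3],
        R$r31 * vec[, 1] + R$r32 * vec[, 2] + R$r33 * vec[, 3])
}

#' Sample rigid-water configurations and Maxwell--Boltzmann velocities
#'
#' Generates `n` rigid 3-site waters in random orientations with site
#' velocities drawn from the Maxwell--Boltzmann distribution at temperature
#' `T`. Modes: `"equilibrium"` draws independent per-site MB velocities
#' (translation, rotation and residual vibration each carry kB T/2 per
#' degree of freedom), `"translation"` gives every site the molecule's MB
#' centre-of-mass velocity (T_rot = 0), `"rotation"` draws a MB angular
#' velocity about the COM principal axes (T_trs = 0).
#'
#' @param n number of molecules
#' @param temperature temperature (K)
#' @param masses a [water_masses()] object (site masses)
#' @param mode `"equilibrium"`, `"translation"` or `"rotation"`
#' @param seed integer seed
#' @param geometry 3 x 3 site-coordinate matrix, default
#'   [water_site_geometry()]
#' @return List with `positions` and `velocities`, both
#'   (n, 3 sites, 3 axes) arrays, ready for [rigid_body_temperatures()].
#' @export
sample_water_velocities <- function(n, temperature,
                                    masses = tip3p_masses(),
                                    mode = c("equilibrium", "translation",
                                             "rotation"),
                                    seed = 1,
                                    geometry = water_site_geometry()) {
  mode <- match.arg(mode)
  stopifnot(inherits(masses, "water_masses"), n >= 1, temperature > 0)
  set.seed(seed)
  m <- c(masses$m_O, masses$m_H, masses$m_H)
  M <- sum(m)
  kT <- .kB * temperature

  R <- .random_rotations(n)
  pos <- array(0, dim = c(n, 3, 3))
  for (s in 1:3) {
    site <- matrix(geometry[s, ], n, 3, byrow = TRUE)
    pos[, s, ] <- .apply_rotations(R, site)
  }

  vel <- array(0, dim = c(n, 3, 3))
  if (mode == "equilibrium") {
    for (s in 1:3) {
      vel[, s, ] <- matrix(stats::rnorm(3 * n, sd = sqrt(kT / m[s])), n, 3)
    }
  } else if (mode == "translation") {
    v_com <- matrix(stats::rnorm(3 * n, sd = sqrt(kT / M)), n, 3)
    for (s in 1:3) vel[, s, ] <- v_com
  } else {
    # MB angular velocity about body principal axes, rotated to the lab frame
    r_com_body <- colSums(m * water_site_geometry_check(geometry)) / M
    body <- sweep(geometry, 2, r_com_body)
    Ibody <- matrix(0, 3, 3)
    for (s in 1:3) {
      r <- body[s, ]
      Ibody <- Ibody + m[s] * (sum(r^2) * diag(3) - tcrossprod(r))
    }
    eig <- eigen(Ibody, symmetric = TRUE)
    if (min(eig$values) < 1e-12 * max(eig$values)) {
      stop("degenerate geometry: collinear sites", call. = FALSE)
    }
    w_body <- matrix(stats::rnorm(3 * n), n, 3) %*%
      diag(sqrt(kT / eig$values)) %*% t(eig$vectors)
    w_lab <- .apply_rotations(R, w_body)
    r_com_lab <- .apply_rotations(R, matrix(r_com_body, n, 3, byrow = TRUE))
    for (s in 1:3) {
      rr <- matrix(pos[, s, ], n, 3) - r_com_lab
      vel[, s, ] <- cbind(w_lab[, 2] * rr[, 3] - w_lab[, 3] * rr[, 2],
                          w_lab[, 3] * rr[, 1] - w_lab[, 1] * rr[, 3],
                          w_lab[, 1] * rr[, 2] - w_lab[, 2] * rr[, 1])
    }
  }
  list(positions = pos, velocities = vel)
}

# internal: geometry sanity pass-through (kept separate for clarity)
water_site_geometry_check <- function(geometry) {
  stopifnot(is.matrix(geometry), all(dim(geometry) == c(3, 3)))
  geometry
}
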