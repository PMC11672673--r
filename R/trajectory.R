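# Trajectory containers, NPT-aware unwrapping, and a Brownian generator.
#
# Positions are stored as a (frames x particles x 3) array in nm, with a
# per-frame orthorhombic box (frames x 3 edge lengths, nm) and a frame
# spacing in ps. Only orthorhombic boxes are supported.

#' Wrapped trajectory container
#'
#' @param positions numeric array, dim (n_frames, n_particles, 3), in nm;
#'   coordinates must satisfy `0 <= x < box edge` frame by frame
#' @param box per-frame box edge lengths: an (n_frames x 3) matrix, or a
#'   length-3 vector (constant box), or a scalar (constant cubic box), nm
#' @param frame_dt time between frames (ps), > 0
#' @return Object of class `wrapped_trajectory`.
#' @export
wrapped_trajectory <- function(positions, box, frame_dt) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[3] == 3L)
  n_frames <- dim(positions)[1]
  if (n_frames < 2L) stop("need >= 2 frames", call. = FALSE)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3L,
                                       byrow = TRUE)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3L)
  if (any(box <= 0)) stop("box edges must be positive", call. = FALSE)
  for (a in 1:3) {
    if (any(positions[, , a] < 0 | positions[, , a] >= box[, a])) {
      stop("positions must be wrapped into [0, box) on every axis",
           call. = FALSE)
    }
  }
  if (!is.numeric(frame_dt) || frame_dt <= 0) {
    stop("frame_dt must be > 0", call. = FALSE)
  }
  structure(list(positions = positions, box = box, frame_dt = frame_dt),
            class = "wrapped_trajectory")
}

#' @export
print.wrapped_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "Wrapped trajectory: %d frames x %d particles, frame_dt = %g ps\n",
    d[1], d[2], x$frame_dt))
  cat(sprintf("  mean box: %.4f x %.4f x %.4f nm\n", mean(x$box[, 1]),
              mean(x$box[, 2]), mean(x$box[, 3])))
  invisible(x)
}

#' Wrap coordinates into the periodic box
#'
#' @param unwrapped array (n_frames, n_particles, 3), nm
#' @param box per-frame box as in [wrapped_trajectory()]
#' @return Array of the same shape with every coordinate in `[0, box)`.
#' @export
wrap_positions <- function(unwrapped, box) {
  n_frames <- dim(unwrapped)[1]
  if (length(box) == 1L) box <- rep(box, 3L)
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3L,
                                       byrow = TRUE)
  out <- unwrapped
  for (a in 1:3) {
    L <- box[, a]
    out[, , a] <- unwrapped[, , a] - L * floor(unwrapped[, , a] / L)
  }
  out
}

#' Unwrap a constant-pressure trajectory
#'
#' Reconstructs continuous particle paths from wrapped coordinates under a
#' fluctuating orthorhombic box. Per axis,
#' \deqn{u_k = w_k - L_k\,\mathrm{round}\!\big((w_k - (L_k/L_{k-1})\,
#'   u_{k-1})/L_k\big),}
#' i.e. the periodic image of the wrapped coordinate closest to the previous
#' unwrapped position scaled by the frame-to-frame box ratio. The box-ratio
#' scaling accounts for barostat coordinate rescaling in constant-pressure
#' MD; for a constant box the scheme reduces to the familiar
#' minimum-image displacement accumulation. It is exact whenever true
#' frame-to-frame displacements stay below half a box edge.
#'
#' @param traj a [wrapped_trajectory()]
#' @param aliasing_fraction reconstructed jumps larger than this fraction of
#'   the box edge trigger a warning that the frame spacing is too sparse
#'   (default 0.45)
#' @return Numeric array (n_frames, n_particles, 3) of unwrapped
#'   coordinates, nm. First frame equals the input.
#' @export
unwrap_npt <- function(traj, aliasing_fraction = 0.45) {
  stopifnot(inherits(traj, "wrapped_trajectory"))
  w <- traj$positions
  box <- traj$box
  n_frames <- dim(w)[1]
  u <- w
  max_frac <- 0
  for (k in 2:n_frames) {
    r <- box[k, ] / box[k - 1, ]
    for (a in 1:3) {
      L <- box[k, a]
      pred <- r[a] * u[k - 1, , a]
      jump <- w[k, , a] - pred
      u[k, , a] <- w[k, , a] - L * round(jump / L)
      frac <- max(abs(u[k, , a] - pred)) / L
      if (frac > max_frac) max_frac <- frac
    }
  }
  if (max_frac > aliasing_fraction) {
    warning(sprintf(
      "possible aliasing: largest frame-to-frame displacement is %.2f of a
box edge; frames may be too sparse for reliable unwrapping", max_frac))
  }
  u
}

#' Generate a Brownian particle system under a fluctuating periodic box
#'
#' Independent Gaussian walkers with per-axis step variance
#' `2 D_true frame_dt`, wrapped each frame into a cubic box whose edge
#' follows a bounded AR(1) fluctuation around `box0`
#' (`L_k = box0 (1 + e_k)`, `e_k = phi e_{k-1} + noise`, stationary sd
#' `box_fluct_rel`, clipped at 3 sd so the box stays positive). The true
#' continuous paths are returned alongside as ground truth.
#'
#' @param D_true diffusion coefficient (nm^2/ns), >= 0
#' @param n_particles number of particles
#' @param n_frames number of frames (>= 2)
#' @param frame_dt frame spacing (ps)
#' @param box0 mean cubic box edge (nm)
#' @param box_fluct_rel relative box fluctuation amplitude, in [0, 0.1]
#' @param seed integer seed
#' @param phi AR(1) coefficient of the box fluctuation (default 0.95)
#' @return List with `trajectory` (a [wrapped_trajectory()]) and `truth`
#'   (unwrapped ground-truth array).
#' @export
generate_brownian_system <- function(D_true, n_particles, n_frames, frame_dt,
                                     box0, box_fluct_rel = 0.003, seed = 1,
                                     phi = 0.95) {
  stopifnot(D_true >= 0, n_particles >= 1, n_frames >= 2, frame_dt > 0,
            box0 > 0, box_fluct_rel >= 0, box_fluct_rel <= 0.1,
            phi >= 0, phi < 1)
  set.seed(seed)
  # box fluctuation
  if (box_fluct_rel > 0) {
    innov_sd <- box_fluct_rel * sqrt(1 - phi^2)
    e <- numeric(n_frames)
    e[1] <- stats::rnorm(1, sd = box_fluct_rel)
    z <- stats::rnorm(n_frames - 1, sd = innov_sd)
    for (k in 2:n_frames) e[k] <- phi * e[k - 1] + z[k - 1]
    e <- pmin(pmax(e, -3 * box_fluct_rel), 3 * box_fluct_rel)
  } else {
    e <- numeric(n_frames)
  }
  Ledge <- box0 * (1 + e)
  box <- matrix(Ledge, nrow = n_frames, ncol = 3L)

  sd_step <- sqrt(2 * D_true * frame_dt / 1000)  # nm; D nm^2/ns, dt ps
  u <- array(0, dim = c(n_frames, n_particles, 3L))
  u[1, , ] <- stats::runif(n_particles * 3L) * Ledge[1]
  if (sd_step > 0) {
    steps <- array(stats::rnorm((n_frames - 1) * n_particles * 3L,
                                sd = sd_step),
                   dim = c(n_frames - 1, n_particles, 3L))
  } else {
    steps <- array(0, dim = c(n_frames - 1, n_particles, 3L))
  }
  for (a in 1:3) {
    u[, , a] <- apply(rbind(u[1, , a, drop = TRUE],
                            matrix(steps[, , a], nrow = n_frames - 1)),
                      2, cumsum)
  }
  w <- wrap_positions(u, box)
  list(trajectory = wrapped_trajectory(w, box, frame_dt), truth = u)
}
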