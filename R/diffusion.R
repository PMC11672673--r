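# Mean-squared displacement and GLS diffusion estimation.
#
# The MSD over all overlapping time origins is computed with the standard
# FFT decomposition. Because overlapping-origin MSD points are strongly
# correlated, the straight-line fit MSD(tau) = 2*dim*D*tau + b uses
# generalized least squares with the exact covariance of the MSD estimator
# for independent Gaussian walkers; the chi-square of the GLS residual gives
# the quality factor Q, which is uniform on [0,1] when the model holds.

# MSD of one 1D signal over lags 0..max_lag (frames), all overlapping
# origins, FFT-based.
.msd_1d_fft <- function(x, max_lag) {
  n <- length(x)
  lag <- 0:max_lag
  # S2(k) = sum_i x_i x_{i+k} via zero-padded FFT autocorrelation
  np <- stats::nextn(2L * n, 2L)
  fx <- stats::fft(c(x, rep(0, np - n)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:(max_lag + 1L)] / np
  # S1(k) = sum_{i=0}^{n-k-1} (x_{i+k}^2 + x_i^2)
  d <- x^2
  cs <- cumsum(d)
  total <- cs[n]
  head_sum <- c(0, cs[seq_len(max_lag)])          # sum of first k squares
  tail_sum <- c(0, total - cs[n - seq_len(max_lag)])  # sum of last k squares
  s1 <- (total - head_sum) + (total - tail_sum)
  (s1 - 2 * s2) / (n - lag)
}

#' Mean-squared displacement curve
#'
#' 3D MSD averaged over all overlapping time origins and all particles.
#'
#' @param unwrapped array (n_frames, n_particles, 3) of continuous
#'   coordinates, nm (see [unwrap_npt()])
#' @param max_lag largest lag time (ps); must be shorter than the trajectory
#' @param frame_dt frame spacing (ps)
#' @return Object of class `msd_curve`: list with `lag_ps`, `msd_nm2`,
#'   `count` (origin-particle pairs per lag), `n_frames`, `n_particles`,
#'   `frame_dt`, and `per_particle` (particles x lags matrix of per-particle
#'   MSDs, used for bootstrap fallbacks).
#' @export
msd <- function(unwrapped, max_lag, frame_dt) {
  stopifnot(is.array(unwrapped), length(dim(unwrapped)) == 3L)
  n_frames <- dim(unwrapped)[1]
  n_particles <- dim(unwrapped)[2]
  if (n_frames < 2L) stop("need >= 2 frames", call. = FALSE)
  max_lag_frames <- floor(max_lag / frame_dt + 1e-9)
  if (max_lag_frames >= n_frames) {
    stop("invalid argument: max_lag must be shorter than the trajectory",
         call. = FALSE)
  }
  if (max_lag_frames < 1L) stop("invalid argument: max_lag < frame_dt",
                                call. = FALSE)
  per_particle <- matrix(0, n_particles, max_lag_frames + 1L)
  for (p in seq_len(n_particles)) {
    acc <- numeric(max_lag_frames + 1L)
    for (a in 1:3) {
      acc <- acc + .msd_1d_fft(unwrapped[, p, a], max_lag_frames)
    }
    per_particle[p, ] <- acc
  }
  lag <- 0:max_lag_frames
  structure(
    list(lag_ps = lag * frame_dt,
         msd_nm2 = colMeans(per_particle),
         count = (n_frames - lag) * n_particles,
         n_frames = n_frames, n_particles = n_particles,
         frame_dt = frame_dt, per_particle = per_particle),
    class = "msd_curve"
  )
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags up to %g ps (%d frames x %d particles)\n",
              length(x$lag_ps), max(x$lag_ps), x$n_frames, x$n_particles))
  invisible(x)
}

# Exact covariance of overlapping-origin MSD estimates for independent
# Gaussian walkers. n, m: lags in frames (n <= m), n_pos: number of frames,
# sigma2: per-axis per-step displacement variance. Returns the 1D covariance;
# the caller divides by (n_signals) = dim * n_particles and multiplies by dim
# as appropriate.
.msd_cov_pair <- function(n, m, n_pos, sigma2) {
  if (n > m) { tmp <- n; n <- m; m <- tmp }
  N <- n_pos - 1L  # steps
  d <- (-(m - 1L)):(n - 1L)
  g <- pmin(n, n - d, m + d)
  cnt <- pmin(N - n, N - m - d) - pmax(0, -d) + 1
  cnt <- pmax(cnt, 0)
  2 * sigma2^2 * sum(cnt * as.numeric(g)^2) /
    ((N - n + 1) * (N - m + 1))
}

.msd_cov_matrix <- function(lags_frames, n_pos, sigma2) {
  K <- length(lags_frames)
  V <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in i:K) {
      V[i, j] <- V[j, i] <- .msd_cov_pair(lags_frames[i], lags_frames[j],
                                          n_pos, sigma2)
    }
  }
  V
}

#' Diffusion coefficient from an MSD curve by generalized least squares
#'
#' Fits `MSD(tau) = 2 dim D tau + b` over lags `>= t_min` (default 20 ps,
#' long enough that short-lag artefacts are excluded). Weighting uses the
#' exact covariance of overlapping-origin MSD estimates for free diffusion
#' of independent Gaussian walkers; the displacement variance entering the
#' covariance is taken from an initial OLS slope and refined once. The
#' quality factor `Q` is the upper-tail chi-square probability of the GLS
#' residual: uniform on [0, 1] (mean 1/2) when the diffusive model holds.
#' If the covariance is numerically ill-conditioned the fit falls back to
#' ordinary least squares with particle-bootstrap errors.
#'
#' @param msd_curve an [msd()] result
#' @param t_min shortest lag used (ps), default 20
#' @param dim dimensionality of the diffusion (3 for bulk, 2 for membranes)
#' @param max_points at most this many lags enter the GLS fit, evenly
#'   subsampled (overlapping lags are highly redundant); default 40
#' @return Object of class `diffusion_fit`: `D` and `se_D` (nm^2/ns), `b`
#'   (intercept, nm^2), `Q`, `chisq`, `dof`, `t_min`, `n_lags`, `method`
#'   (`"gls"` or `"ols_bootstrap"`).
#' @export
fit_diffusion <- function(msd_curve, t_min = 20, dim = 3, max_points = 40) {
  stopifnot(inherits(msd_curve, "msd_curve"), dim %in% c(1, 2, 3))
  sel <- which(msd_curve$lag_ps >= t_min)
  if (length(sel) < 3L) {
    stop("insufficient data: need >= 3 lags at or beyond t_min",
         call. = FALSE)
  }
  if (length(sel) > max_points) {
    sel <- sel[unique(round(seq(1, length(sel), length.out = max_points)))]
  }
  tau <- msd_curve$lag_ps[sel]
  y <- msd_curve$msd_nm2[sel]
  lags_frames <- as.integer(round(tau / msd_curve$frame_dt))
  X <- cbind(b = 1, tau = tau)

  # initial OLS slope -> step variance for the covariance model
  ols <- stats::lm.fit(X, y)
  slope <- ols$coefficients["tau"]         # nm^2 / ps
  D_ols <- slope / (2 * dim) * 1000       # nm^2 / ns

  gls_pass <- function(sigma2) {
    # cov of the dim-summed, particle-averaged MSD: dim * cov_1d / P
    V <- .msd_cov_matrix(lags_frames, msd_curve$n_frames, sigma2) *
      dim / msd_curve$n_particles
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Xw <- backsolve(R, X, transpose = TRUE)
    yw <- backsolve(R, y, transpose = TRUE)
    fit <- stats::lm.fit(Xw, yw)
    XtX_inv <- chol2inv(chol(crossprod(Xw)))
    resid <- yw - Xw %*% fit$coefficients
    list(beta = fit$coefficients, cov = XtX_inv,
         chisq = sum(resid^2))
  }

  method <- "gls"
  res <- NULL
  if (is.finite(D_ols) && D_ols > 0) {
    sigma2 <- 2 * D_ols * msd_curve$frame_dt / 1000
    res <- gls_pass(sigma2)
    if (!is.null(res)) {
      D1 <- res$beta[[2]] / (2 * dim) * 1000
      if (is.finite(D1) && D1 > 0) {
        res2 <- gls_pass(2 * D1 * msd_curve$frame_dt / 1000)
        if (!is.null(res2)) res <- res2
      }
    }
  }

  if (is.null(res)) {
    # OLS fallback with particle-bootstrap errors
    method <- "ols_bootstrap"
    beta <- ols$coefficients
    P <- msd_curve$n_particles
    B <- 200L
    slopes <- numeric(B)
    for (b in seq_len(B)) {
      idx <- sample.int(P, P, replace = TRUE)
      yb <- colMeans(msd_curve$per_particle[idx, sel + 0L, drop = FALSE])
      slopes[b] <- stats::lm.fit(X, yb)$coefficients["tau"]
    }
    se_slope <- stats::sd(slopes)
    var_y <- apply(msd_curve$per_particle[, sel, drop = FALSE], 2,
                   stats::var) / P
    resid <- y - X %*% beta
    chisq <- sum(resid^2 / pmax(var_y, .Machine$double.eps))
    res <- list(beta = beta,
                cov = matrix(c(NA, NA, NA, se_slope^2), 2, 2),
                chisq = chisq)
  }

  dof <- length(tau) - 2L
  D <- unname(res$beta[[2]]) / (2 * dim) * 1000
  se_D <- sqrt(res$cov[2, 2]) / (2 * dim) * 1000
  Q <- stats::pchisq(res$chisq, df = dof, lower.tail = FALSE)
  structure(
    list(D = D, se_D = se_D, b = unname(res$beta[1]), Q = Q,
         chisq = res$chisq, dof = dof, t_min = t_min, n_lags = length(tau),
         dim = dim, method = method),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("D = %.4g +/- %.2g nm^2/ns  (Q = %.3f, %d lags >= %g ps, %s)\n",
              x$D, x$se_D, x$Q, x$n_lags, x$t_min, x$method))
  invisible(x)
}

# kJ/mol * ns / nm^3 -> Pa s
.eta_unit_to_pa_s <- 1e3 / 6.02214076e23 / (1e-27 / 1e-9)

#' Yeh--Hummer finite-size extrapolation
#'
#' In a periodic cubic box the measured self-diffusion coefficient is
#' depressed by hydrodynamic self-interaction:
#' `D(L) = D_inf - kB T xi / (6 pi eta L)` with `xi = 2.837297`. A straight
#' -line fit of `D` against `1/L` gives the infinite-size coefficient
#' `D_inf` (intercept) and the shear viscosity from the slope,
#' `eta = kB T xi / (6 pi |slope|)`.
#'
#' @param L cubic box edges (nm), >= 2 distinct values
#' @param D measured diffusion coefficients (nm^2/ns)
#' @param temperature temperature (K)
#' @return Object of class `finite_size_fit`: `D_inf` and `se_D_inf`
#'   (nm^2/ns), `slope` (nm^3/ns, expected < 0), `eta_pa_s` (shear
#'   viscosity, Pa s; `Inf` when the slope is >= 0), `temperature`,
#'   `residuals`.
#' @export
finite_size_extrapolation <- function(L, D, temperature) {
  stopifnot(length(L) == length(D), length(L) >= 2L, temperature > 0)
  if (length(unique(L)) < 2L) {
    stop("singular fit: need >= 2 distinct box sizes", call. = FALSE)
  }
  inv_L <- 1 / L
  fit <- stats::lm(D ~ inv_L)
  beta <- stats::coef(fit)
  se <- if (length(L) > 2L) {
    X <- cbind(1, inv_L)
    s2 <- sum(stats::residuals(fit)^2) / (length(L) - 2L)
    sqrt(diag(solve(crossprod(X))) * s2)
  } else {
    c(NA, NA)
  }
  slope <- unname(beta[2])
  eta_raw <- if (slope < 0) {
    .kB * temperature * .xi_cubic / (6 * pi * abs(slope))
  } else {
    Inf
  }
  structure(
    list(D_inf = unname(beta[1]), se_D_inf = unname(se[1]), slope = slope,
         eta_pa_s = eta_raw * .eta_unit_to_pa_s, temperature = temperature,
         residuals = unname(stats::residuals(fit))),
    class = "finite_size_fit"
  )
}

#' @export
print.finite_size_fit <- function(x, ...) {
  cat(sprintf("D_inf = %.4g nm^2/ns, slope = %.4g nm^3/ns, eta = %.4g mPa s\n",
              x$D_inf, x$slope, x$eta_pa_s * 1e3))
  invisible(x)
}

#' Predicted box-size-dependent diffusion coefficient
#'
#' The Yeh--Hummer prediction `D(L) = D_inf - kB T xi/(6 pi eta L)`; inverse
#' of [finite_size_extrapolation()], useful for generating synthetic D(L)
#' curves with a known viscosity.
#'
#' @param D_inf infinite-size diffusion coefficient (nm^2/ns)
#' @param eta_pa_s shear viscosity (Pa s)
#' @param L box edges (nm)
#' @param temperature temperature (K)
#' @return Predicted D values (nm^2/ns).
#' @export
yeh_hummer_prediction <- function(D_inf, eta_pa_s, L, temperature) {
  stopifnot(eta_pa_s > 0, all(L > 0), temperature > 0)
  eta_raw <- eta_pa_s / .eta_unit_to_pa_s
  D_inf - .kB * temperature * .xi_cubic / (6 * pi * eta_raw * L)
}
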