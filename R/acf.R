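# Autocorrelation functions and relaxation-time estimators.
#
# tau_int controls the effective number of independent samples of a time
# series (statistical error ~ sd * sqrt(2 tau_int / T)); tau_exp is the
# slowest relaxation time, read off a log-linear fit of the ACF tail.

# sum_i x_i x_{i+k} for k = 0..max_lag via zero-padded FFT
.autocov_fft <- function(x, max_lag) {
  n <- length(x)
  np <- stats::nextn(2L * n, 2L)
  fx <- stats::fft(c(x, rep(0, np - n)))
  Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:(max_lag + 1L)] / np
}

.new_acf <- function(values, frame_dt, type, n) {
  structure(list(lag_ps = (seq_along(values) - 1L) * frame_dt,
                 values = values, frame_dt = frame_dt, type = type, n = n),
            class = "series_acf")
}

#' @export
print.series_acf <- function(x, ...) {
  cat(sprintf("%s ACF: %d lags up to %g ps (n = %d)\n",
              if (x$type == "vdsb") "Dihedral (van der Spoel-Berendsen)"
              else "Linear", length(x$values), max(x$lag_ps), x$n))
  invisible(x)
}

#' Normalized autocorrelation function of a linear series
#'
#' Mean-subtracted, variance-normalized ACF computed by fast convolution,
#' with unbiased per-lag normalization: `rho_k = c_k / c_0` with
#' `c_k = sum_i (x_i - xbar)(x_{i+k} - xbar) / (n - k)` and
#' `c_0` the usual 1/n variance, so `rho_0 = 1` exactly.
#'
#' @param series a non-circular [cv_series()]
#' @param max_lag largest lag (ps)
#' @return A `series_acf` object with `lag_ps` and `values`.
#' @export
autocorrelation <- function(series, max_lag) {
  stopifnot(inherits(series, "cv_series"))
  if (series$circular) {
    stop("type error: use vdsb_dihedral_acf() for circular series",
         call. = FALSE)
  }
  x <- series$values
  n <- length(x)
  max_lag_frames <- min(floor(max_lag / series$frame_dt + 1e-9), n - 1L)
  x <- x - mean(x)
  s2 <- .autocov_fft(x, max_lag_frames)
  if (s2[1] <= 0 || !is.finite(s2[1])) {
    stop("degenerate series: zero variance", call. = FALSE)
  }
  c0 <- s2[1] / n
  ck <- s2 / (n - 0:max_lag_frames)
  .new_acf(ck / c0, series$frame_dt, "linear", n)
}

#' Van der Spoel--Berendsen dihedral autocorrelation function
#'
#' `C(t) = < cos(theta(t0 + t) - theta(t0)) >` over all time origins,
#' the natural ACF for a circular variable (no mean subtraction; `C(0) = 1`
#' exactly). For a confined dihedral, `C(t)` decays to a plateau near the
#' order parameter S_D^2 rather than to 0; `normalize = "plateau"` rescales
#' to `(C - S2)/(1 - S2)` using the series' own S_D^2.
#'
#' @param series a circular [cv_series()] (degrees)
#' @param max_lag largest lag (ps)
#' @param normalize `"none"` (default) or `"plateau"`
#' @return A `series_acf` object.
#' @export
vdsb_dihedral_acf <- function(series, max_lag,
                              normalize = c("none", "plateau")) {
  stopifnot(inherits(series, "cv_series"))
  normalize <- match.arg(normalize)
  if (!series$circular) {
    stop("type error: vdsb_dihedral_acf() requires a circular series",
         call. = FALSE)
  }
  th <- series$values * pi / 180
  n <- length(th)
  max_lag_frames <- min(floor(max_lag / series$frame_dt + 1e-9), n - 1L)
  cc <- .autocov_fft(cos(th), max_lag_frames)
  ss <- .autocov_fft(sin(th), max_lag_frames)
  vals <- (cc + ss) / (n - 0:max_lag_frames)
  if (normalize == "plateau") {
    s2 <- dihedral_order_parameter(series)
    if (s2 >= 1 - 1e-12) stop("degenerate series: S_D^2 = 1", call. = FALSE)
    vals <- (vals - s2) / (1 - s2)
  }
  .new_acf(vals, series$frame_dt, "vdsb", n)
}

#' Dihedral order parameter S_D^2
#'
#' Squared circular resultant
#' `S_D^2 = <cos theta>^2 + <sin theta>^2`, in `[0, 1]`: 1 for a delta
#' -distributed angle, 0 for a uniform (or symmetrically cancelling)
#' distribution. This is the standard circular concentration measure; a
#' concentrated single-well dihedral scores high, a bimodal one low.
#'
#' @param series a circular [cv_series()], or a numeric vector of angles in
#'   degrees
#' @return S_D^2 in `[0, 1]`.
#' @export
dihedral_order_parameter <- function(series) {
  th <- if (inherits(series, "cv_series")) {
    if (!series$circular) stop("type error: series is not circular",
                               call. = FALSE)
    series$values
  } else {
    as.numeric(series)
  }
  if (length(th) == 0L) stop("invalid argument: empty series", call. = FALSE)
  th <- th * pi / 180
  mean(cos(th))^2 + mean(sin(th))^2
}

# Sokal automatic window: smallest W with W >= c * tau_int(W) (in frames)
.sokal_window <- function(rho, c_sokal = 5) {
  tau_cum <- 0.5 + cumsum(rho[-1])  # tau_int(W) for W = 1..K
  W <- which(seq_along(tau_cum) >= c_sokal * tau_cum)[1]
  if (is.na(W)) {
    warning("Sokal window exceeds available lags; ACF truncated")
    W <- length(tau_cum)
  }
  W
}

.first_negative_window <- function(rho) {
  neg <- which(rho[-1] < 0)[1]
  if (is.na(neg)) {
    warning("no negative ACF value; window truncated at the last lag")
    length(rho) - 1L
  } else {
    max(neg - 1L, 1L)
  }
}

#' Integrated autocorrelation time
#'
#' `tau_int = frame_dt (1/2 + sum_{k=1}^{W} rho_k)`, with the truncation
#' window `W` chosen automatically: the Sokal rule (smallest `W >= c *
#' tau_int(W)`, default `c = 5`) or the first negative ACF value. With
#' several replicas, each replica's ACF is integrated separately and the SE
#' is the across-replica standard deviation over `sqrt(n_replicas)`.
#'
#' @param acf a `series_acf`, or a list of them (replicas sharing
#'   `frame_dt`)
#' @param window_rule `"sokal"` (default) or `"first_negative"`
#' @param c_sokal Sokal window constant (default 5)
#' @return Object of class `act_estimate`: `tau_int` (ns), `se_int` (ns; NA
#'   for a single replica), `window_used` (lag count, largest across
#'   replicas), `per_replica` (ns), `n_replicas`.
#' @export
integrated_act <- function(acf, window_rule = c("sokal", "first_negative"),
                           c_sokal = 5) {
  window_rule <- match.arg(window_rule)
  acfs <- if (inherits(acf, "series_acf")) list(acf) else acf
  stopifnot(length(acfs) >= 1L,
            all(vapply(acfs, inherits, logical(1), "series_acf")))
  dts <- vapply(acfs, `[[`, numeric(1), "frame_dt")
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("replicas must share frame_dt", call. = FALSE)
  }
  one <- function(a) {
    W <- if (window_rule == "sokal") .sokal_window(a$values, c_sokal)
         else .first_negative_window(a$values)
    tau_frames <- 0.5 + sum(a$values[2:(W + 1L)])
    c(tau = tau_frames * a$frame_dt / 1000, W = W)  # ns
  }
  res <- vapply(acfs, one, c(tau = 0, W = 0))
  taus <- res["tau", ]
  nrep <- length(taus)
  structure(
    list(tau_int = mean(taus),
         se_int = if (nrep > 1L) stats::sd(taus) / sqrt(nrep) else NA_real_,
         window_used = as.integer(max(res["W", ])),
         per_replica = taus, n_replicas = nrep,
         window_rule = window_rule),
    class = "act_estimate"
  )
}

#' @export
print.act_estimate <- function(x, ...) {
  cat(sprintf("tau_int = %.4g ns", x$tau_int))
  if (!is.na(x$se_int)) cat(sprintf(" (SE %.2g, %d replicas)", x$se_int,
                                    x$n_replicas))
  cat(sprintf("; window %d lags [%s]\n", x$window_used, x$window_rule))
  invisible(x)
}

#' Exponential autocorrelation time from a log-linear tail fit
#'
#' Fits `ln C(t)` against `t` by least squares over `fit_range` and returns
#' `tau_exp = -1/slope`. The default range is the set of lags where
#' `C` lies in `[0.05, 0.5]`, a reasonably linear regime in log space for
#' the slowest process.
#'
#' @param acf a `series_acf`
#' @param fit_range length-2 numeric `(t_lo, t_hi)` in ps, or NULL for the
#'   automatic range
#' @return List of class `act_exp`: `tau_exp` (ns), `se_exp` (ns),
#'   `fit_range` (ps), `n_points`.
#' @export
exponential_act <- function(acf, fit_range = NULL) {
  stopifnot(inherits(acf, "series_acf"))
  if (is.null(fit_range)) {
    sel <- which(acf$values >= 0.05 & acf$values <= 0.5)
    if (length(sel) < 2L) {
      stop("invalid range: automatic range [0.05, 0.5] holds fewer than 2 ",
           "lags; give fit_range explicitly", call. = FALSE)
    }
    fit_range <- range(acf$lag_ps[sel])
  }
  sel <- which(acf$lag_ps >= fit_range[1] & acf$lag_ps <= fit_range[2])
  if (length(sel) < 2L) {
    stop("invalid range: fewer than 2 lags in fit_range", call. = FALSE)
  }
  C <- acf$values[sel]
  if (any(C <= 0)) {
    stop("invalid range: non-positive ACF values inside fit_range",
         call. = FALSE)
  }
  t <- acf$lag_ps[sel]
  fit <- stats::lm(log(C) ~ t)
  slope <- stats::coef(fit)[["t"]]
  if (slope >= 0) stop("invalid range: ACF does not decay over fit_range",
                       call. = FALSE)
  se_slope <- if (length(sel) > 2L) {
    X <- cbind(1, t)
    s2 <- sum(stats::residuals(fit)^2) / (length(sel) - 2L)
    sqrt(solve(crossprod(X))[2, 2] * s2)
  } else {
    NA_real_
  }
  structure(
    list(tau_exp = -1 / slope / 1000, se_exp = se_slope / slope^2 / 1000,
         fit_range = fit_range, n_points = length(sel)),
    class = "act_exp"
  )
}

#' @export
print.act_exp <- function(x, ...) {
  cat(sprintf("tau_exp = %.4g ns (SE %.2g), fit over [%g, %g] ps, %d lags\n",
              x$tau_exp, x$se_exp, x$fit_range[1], x$fit_range[2],
              x$n_points))
  invisible(x)
}

#' Standard error of the mean by block averaging
#'
#' Averages the series over blocks of geometrically growing size; the naive
#' SEM of the block means rises with block size while blocks remain
#' correlated and plateaus once blocks are effectively independent. The
#' plateau value (detected as the point where successive block doublings
#' change the SEM by < 5%, averaged over the plateau tail; the largest-block
#' estimate with a warning if no plateau is reached) estimates the true SEM
#' without requiring the autocorrelation time explicitly.
#'
#' @param series a [cv_series()] or numeric vector with >= 16 samples
#' @param min_blocks smallest number of blocks per size (default 16)
#' @return List of class `block_sem`: `sem`, `block_size` (frames, start of
#'   the plateau), `curve` (data.frame of block size vs SEM), `plateau`
#'   (logical).
#' @export
block_sem <- function(series, min_blocks = 16L) {
  x <- if (inherits(series, "cv_series")) series$values
       else as.numeric(series)
  n <- length(x)
  if (n < 16L) stop("insufficient data: need >= 16 samples", call. = FALSE)
  sizes <- 2^(0:floor(log2(n / min_blocks)))
  sems <- vapply(sizes, function(b) {
    nb <- floor(n / b)
    means <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    stats::sd(means) / sqrt(nb)
  }, numeric(1))
  if (sems[length(sems)] == 0) {  # constant series
    return(structure(list(sem = 0, block_size = sizes[1],
                          curve = data.frame(block_size = sizes, sem = sems),
                          plateau = TRUE),
                     class = "block_sem"))
  }
  rel_step <- diff(sems) / sems[-length(sems)]
  plateau_at <- which(rel_step < 0.05)[1]
  plateau <- !is.na(plateau_at)
  if (!plateau) {
    warning("no SEM plateau reached; reporting the largest-block estimate ",
            "(series may be too short for its correlation time)")
    sem <- sems[length(sems)]
    bs <- sizes[length(sizes)]
  } else {
    sem <- mean(sems[plateau_at:length(sems)])
    bs <- sizes[plateau_at]
  }
  structure(list(sem = sem, block_size = bs,
                 curve = data.frame(block_size = sizes, sem = sems),
                 plateau = plateau),
            class = "block_sem")
}

#' @export
print.block_sem <- function(x, ...) {
  cat(sprintf("block-average SEM = %.4g (plateau from block size %d%s)\n",
              x$sem, x$block_size,
              if (x$plateau) "" else "; no plateau reached"))
  invisible(x)
}

#' Straight-line fit of relaxation time against sqrt(mass)
#'
#' Solute relaxation times in a mass-scaled solvent follow
#' `tau = a + b sqrt(m_tot)`: `b` measures solute--solvent friction and the
#' intercept `a` is the internal-friction floor -- the residual relaxation
#' time that persists as the solvent mass (hence viscosity) is extrapolated
#' to zero, which bounds the achievable speed-up.
#'
#' @param m_tot solvent molecular masses (g/mol), >= 2 distinct values
#' @param tau relaxation times (ns)
#' @param se optional standard errors of `tau` (ns) for weighted fitting
#' @return Object of class `internal_friction_fit`: `a`, `b`, `se_a`,
#'   `se_b`, `cov`, `n_points`.
#' @export
internal_friction_fit <- function(m_tot, tau, se = NULL) {
  stopifnot(length(m_tot) == length(tau))
  if (length(unique(m_tot)) < 2L) {
    stop("insufficient data: need >= 2 distinct m_tot", call. = FALSE)
  }
  sqrt_m <- sqrt(m_tot)
  w <- if (!is.null(se)) {
    stopifnot(length(se) == length(tau), all(se > 0))
    1 / se^2
  } else {
    rep(1, length(tau))
  }
  fit <- stats::lm(tau ~ sqrt_m, weights = w)
  beta <- stats::coef(fit)
  # with stated SEs the weights are absolute inverse variances, so the
  # parameter covariance is (X' W X)^-1 without a residual-variance factor
  X <- cbind(1, sqrt_m)
  V <- if (!is.null(se)) {
    solve(t(X) %*% (w * X))
  } else if (length(tau) > 2L) {
    s2 <- sum(stats::residuals(fit)^2) / (length(tau) - 2L)
    solve(crossprod(X)) * s2
  } else {
    matrix(NA_real_, 2, 2)
  }
  structure(
    list(a = unname(beta[1]), b = unname(beta[2]),
         se_a = sqrt(V[1, 1]), se_b = sqrt(V[2, 2]), cov = unname(V),
         n_points = length(tau)),
    class = "internal_friction_fit"
  )
}

#' @export
print.internal_friction_fit <- function(x, ...) {
  cat(sprintf(
    "tau = a + b sqrt(m): a = %.4g ns (SE %.2g), b = %.4g ns/sqrt(g/mol) (SE %.2g)\n",
    x$a, x$se_a, x$b, x$se_b))
  invisible(x)
}
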