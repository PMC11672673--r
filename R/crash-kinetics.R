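# Poisson crash-rate estimation from censored replica outcomes.
#
# Integration failures ("crashes") are modelled as a Poisson process with
# exponential waiting times. A replica either crashes at time t (event) or
# ends intact at t (censored); both contribute their time at risk to the
# likelihood. The MLE is k_hat = n_crash / sum(t_i), with Cramer-Rao
# standard error k_hat / sqrt(n_crash).

#' Censored crash records
#'
#' @param t per-replica outcome times (ns), > 0: crash time if `crashed`,
#'   end-of-run time otherwise
#' @param crashed logical vector, same length as `t`
#' @return A data.frame of class `crash_records` with columns `t`, `crashed`.
#' @export
crash_records <- function(t, crashed) {
  stopifnot(length(t) == length(crashed))
  if (length(t) == 0L) stop("invalid argument: empty record set",
                            call. = FALSE)
  t <- as.numeric(t)
  crashed <- as.logical(crashed)
  if (any(!is.finite(t) | t <= 0)) {
    stop("invalid argument: all times must be positive and finite",
         call. = FALSE)
  }
  if (anyNA(crashed)) stop("invalid argument: crashed must be TRUE/FALSE",
                           call. = FALSE)
  structure(data.frame(t = t, crashed = crashed),
            class = c("crash_records", "data.frame"))
}

#' Read crash records from CSV
#'
#' Expects columns `time_ns` and `crashed` (logical or 0/1); a `replica_id`
#' column is allowed and ignored.
#'
#' @param path CSV file path
#' @return A [crash_records()] object.
#' @export
read_crash_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ns", "crashed")
  if (!all(need %in% names(df))) {
    stop("parse error in ", path, ": need columns time_ns, crashed",
         call. = FALSE)
  }
  crash_records(df$time_ns, df$crashed)
}

#' Maximum-likelihood crash-rate estimate
#'
#' For censored exponential waiting times the MLE of the rate is
#' \deqn{\hat k = n_{crash} / \sum_i t_i,}
#' summing the times of crashed and intact replicas alike. The standard
#' error is the Cramer-Rao bound \eqn{\hat k/\sqrt{n_{crash}}}. With zero
#' crashes the MLE is 0, the SE is undefined, and a one-sided upper 95%
#' bound \eqn{\ln(20)/\sum_i t_i} is reported instead.
#'
#' @param records a [crash_records()] object (or data.frame with `t`,
#'   `crashed`)
#' @param n_molecules optional number of water molecules in the simulated
#'   system; if given, rate and SE are normalized to per (ns x 1000
#'   molecules)
#' @return An object of class `crash_rate_estimate`: list with `k_hat`, `se`
#'   (NA when `n_crash = 0`), `upper95` (only meaningful at `n_crash = 0`),
#'   `n`, `n_crash`, `total_time`, `n_molecules`, `normalized`.
#' @export
#' @examples
#' r <- crash_records(c(1, 3, 5, 5), c(TRUE, TRUE, FALSE, FALSE))
#' estimate_crash_rate(r)   # 2/14 per ns
estimate_crash_rate <- function(records, n_molecules = NULL) {
  if (!inherits(records, "crash_records")) {
    records <- crash_records(records$t, records$crashed)
  }
  n <- nrow(records)
  n_crash <- sum(records$crashed)
  total_time <- sum(records$t)
  k_hat <- n_crash / total_time
  se <- if (n_crash >= 1L) k_hat / sqrt(n_crash) else NA_real_
  upper95 <- if (n_crash == 0L) log(20) / total_time else NA_real_
  scale <- 1
  normalized <- FALSE
  if (!is.null(n_molecules)) {
    stopifnot(is.numeric(n_molecules), n_molecules > 0)
    scale <- 1000 / n_molecules
    normalized <- TRUE
  }
  structure(
    list(k_hat = k_hat * scale, se = se * scale, upper95 = upper95 * scale,
         n = n, n_crash = n_crash, total_time = total_time,
         n_molecules = if (is.null(n_molecules)) NA_real_ else n_molecules,
         normalized = normalized),
    class = "crash_rate_estimate"
  )
}

#' @export
print.crash_rate_estimate <- function(x, ...) {
  unit <- if (x$normalized) "(ns x 1000 molecules)^-1" else "ns^-1"
  cat(sprintf("Crash rate: %g %s (%d crashes / %d replicas, %g ns at risk)\n",
              x$k_hat, unit, x$n_crash, x$n, x$total_time))
  if (x$n_crash > 0) cat(sprintf("  SE (Cramer-Rao): %g %s\n", x$se, unit))
  else cat(sprintf("  no crashes observed; upper 95%% bound %g %s\n",
                   x$upper95, unit))
  invisible(x)
}

#' Simulate censored crash records
#'
#' Draws exponential waiting times with rate `k_true`; replicas whose
#' waiting time exceeds `t_end` are censored at `t_end`.
#'
#' @param k_true true crash rate (per ns), >= 0
#' @param n number of replicas, >= 1
#' @param t_end run length (ns), > 0
#' @param seed integer seed (required, for reproducibility)
#' @return A [crash_records()] object.
#' @export
simulate_crash_records <- function(k_true, n, t_end, seed) {
  stopifnot(k_true >= 0, n >= 1, t_end > 0)
  set.seed(seed)
  if (k_true == 0) {
    return(crash_records(rep(t_end, n), rep(FALSE, n)))
  }
  w <- stats::rexp(n, rate = k_true)
  crashed <- w < t_end
  crash_records(ifelse(crashed, w, t_end), crashed)
}

#' Fit the exponential mass dependence of the crash rate
#'
#' At fixed repartitioning and time step, the crash rate falls approximately
#' exponentially with the molecular mass, `k = A exp(-c m_tot)`. The model is
#' fitted as a weighted straight line in log space,
#' `ln k_hat = ln_A - c m_tot`, with weights from error propagation of the
#' Cramer-Rao SEs (`sigma_ln k = se/k_hat`). Zero-rate points carry no
#' information about `ln k` and are dropped with a warning.
#'
#' @param m_tot molecular masses (g/mol)
#' @param estimates list of [estimate_crash_rate()] results (one per mass),
#'   or a data.frame with columns `k_hat`, `se`
#' @param m_r repartitioned mass this fit belongs to (bookkeeping only)
#' @return An object of class `exp_mass_model`: list with `ln_A`, `c`
#'   (stored signed, expected > 0), `cov` (2x2 covariance of (ln_A, c)),
#'   `m_r`, `n_points`.
#' @export
fit_exp_mass_model <- function(m_tot, estimates, m_r = NA_real_) {
  if (is.data.frame(estimates)) {
    k_hat <- estimates$k_hat
    se <- estimates$se
  } else {
    k_hat <- vapply(estimates, `[[`, numeric(1), "k_hat")
    se <- vapply(estimates, `[[`, numeric(1), "se")
  }
  stopifnot(length(m_tot) == length(k_hat))
  usable <- is.finite(k_hat) & k_hat > 0
  if (any(!usable)) {
    warning(sum(!usable), " zero-rate point(s) excluded from log-space fit")
  }
  if (sum(usable) < 2L) {
    stop("insufficient data: need >= 2 points with k_hat > 0", call. = FALSE)
  }
  m <- m_tot[usable]
  y <- log(k_hat[usable])
  sig <- se[usable] / k_hat[usable]
  have_se <- all(is.finite(sig) & sig > 0)
  w <- if (have_se) 1 / sig^2 else rep(1, length(m))
  fit <- stats::lm(y ~ m, weights = w)
  beta <- stats::coef(fit)
  # Cramer-Rao SEs are absolute, so no residual-variance rescaling
  V <- if (have_se || length(m) == 2L) {
    X <- cbind(1, m)
    solve(t(X) %*% (w * X))
  } else {
    stats::vcov(fit)
  }
  # c = -slope; flip the slope's covariance signs accordingly
  cov_lnA_c <- matrix(c(V[1, 1], -V[1, 2], -V[2, 1], V[2, 2]), 2, 2,
                      dimnames = list(c("ln_A", "c"), c("ln_A", "c")))
  structure(
    list(ln_A = unname(beta[1]), c = -unname(beta[2]), cov = cov_lnA_c,
         m_r = m_r, n_points = length(m)),
    class = "exp_mass_model"
  )
}

#' @export
print.exp_mass_model <- function(x, ...) {
  cat(sprintf(
    "Exponential crash-rate model: ln k = %g - %g * m_tot (%d points",
    x$ln_A, x$c, x$n_points))
  if (is.finite(x$m_r)) cat(sprintf(", m_r = %g", x$m_r))
  cat(")\n")
  invisible(x)
}

#' Mass at which a fitted model reaches a target crash rate
#'
#' Inverts `k = A exp(-c m_tot)` for `m_tot`. Evaluating over a family of
#' fits at several repartitioned masses traces an iso-stability contour in
#' the (m_r, m_tot) plane.
#'
#' @param model an [fit_exp_mass_model()] result
#' @param k_target target crash rate, > 0 (same units as the fitted rates)
#' @return Molecular mass `m_tot = (ln_A - ln k_target)/c` (g/mol).
#' @export
iso_crash_mass <- function(model, k_target) {
  stopifnot(inherits(model, "exp_mass_model"))
  if (!is.numeric(k_target) || any(k_target <= 0)) {
    stop("invalid argument: k_target must be > 0", call. = FALSE)
  }
  if (abs(model$c) < 1e-10) {
    stop("no solution: fitted decay constant c is 0 (rate does not depend ",
         "on mass)", call. = FALSE)
  }
  (model$ln_A - log(k_target)) / model$c
}
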