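# Histogram free energies and replica-based distribution comparison.

#' Free-energy profile from histogram counts
#'
#' `G_i = -kB T ln p_i`, with `p_i` the proportion of samples in equal
#' -width bin `i`, shifted so the lowest finite value is 0. Empty bins are
#' masked (`NA`), not set to zero.
#'
#' @param series a [cv_series()] or numeric vector
#' @param bin_edges strictly increasing bin-edge vector, or a single bin
#'   count (equal-width bins over the data range; for circular series, 72
#'   bins over (-180, 180] by default)
#' @param temperature temperature (K)
#' @return Object of class `fe_profile`: `d` (bin centers), `p`
#'   (proportions, summing to 1 over observed samples), `G` (kJ/mol, min 0,
#'   NA in empty bins), `counts`, `temperature`.
#' @export
#' @examples
#' x <- c(rep(0.5, 100), rep(1.5, 100))
#' free_energy_profile(x, bin_edges = c(0, 1, 2), temperature = 310)
free_energy_profile <- function(series, bin_edges = NULL, temperature) {
  circular <- inherits(series, "cv_series") && series$circular
  x <- if (inherits(series, "cv_series")) series$values
       else as.numeric(series)
  stopifnot(temperature > 0)
  if (is.null(bin_edges)) {
    bin_edges <- if (circular) seq(-180, 180, by = 5) else
      stats::nclass.FD(x)
  }
  if (length(bin_edges) == 1L) {
    bin_edges <- seq(min(x), max(x), length.out = bin_edges + 1L)
    bin_edges[length(bin_edges)] <- bin_edges[length(bin_edges)] +
      1e-9 * diff(range(x))  # include the max
  }
  stopifnot(all(diff(bin_edges) > 0))
  idx <- findInterval(x, bin_edges, left.open = TRUE, rightmost.closed = FALSE)
  inside <- idx >= 1L & idx <= length(bin_edges) - 1L
  if (!any(inside)) stop("empty histogram: all samples outside bins",
                         call. = FALSE)
  counts <- tabulate(idx[inside], nbins = length(bin_edges) - 1L)
  p <- counts / sum(counts)
  G <- ifelse(counts > 0, -.kB * temperature * log(pmax(p, 0)), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  structure(
    list(d = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
         p = p, G = G, counts = counts, bin_edges = bin_edges,
         temperature = temperature),
    class = "fe_profile"
  )
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf(
    "Free-energy profile: %d bins (%d occupied), T = %g K, max G = %.3g kJ/mol\n",
    length(x$d), sum(x$counts > 0), x$temperature, max(x$G, na.rm = TRUE)))
  invisible(x)
}

#' 2D free-energy surface over two collective variables
#'
#' Histogram free energies on a (phi, psi)-style grid. Two surfaces built on
#' identical edges can be subtracted bin-by-bin with [fe_difference()].
#'
#' @param x,y paired samples of the two variables
#' @param bin_edges_x,bin_edges_y bin-edge vectors (see
#'   [free_energy_profile()])
#' @param temperature temperature (K)
#' @return Object of class `fe_surface`: `G` matrix (rows = x bins), `p`,
#'   `counts`, bin centers `dx`, `dy`, edges, `temperature`.
#' @export
free_energy_surface <- function(x, y, bin_edges_x, bin_edges_y, temperature) {
  stopifnot(length(x) == length(y), temperature > 0,
            all(diff(bin_edges_x) > 0), all(diff(bin_edges_y) > 0))
  ix <- findInterval(x, bin_edges_x, left.open = TRUE)
  iy <- findInterval(y, bin_edges_y, left.open = TRUE)
  nx <- length(bin_edges_x) - 1L
  ny <- length(bin_edges_y) - 1L
  inside <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  if (!any(inside)) stop("empty histogram: all samples outside bins",
                         call. = FALSE)
  counts <- matrix(tabulate((iy[inside] - 1L) * nx + ix[inside],
                            nbins = nx * ny), nx, ny)
  p <- counts / sum(counts)
  G <- ifelse(counts > 0, -.kB * temperature * log(pmax(p, 0)), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  structure(
    list(G = G, p = p, counts = counts,
         dx = (bin_edges_x[-1] + bin_edges_x[-(nx + 1L)]) / 2,
         dy = (bin_edges_y[-1] + bin_edges_y[-(ny + 1L)]) / 2,
         bin_edges_x = bin_edges_x, bin_edges_y = bin_edges_y,
         temperature = temperature),
    class = "fe_surface"
  )
}

#' Difference of two free-energy maps on shared bins
#'
#' @param a,b `fe_profile` or `fe_surface` objects built on identical bin
#'   edges
#' @return `G_a - G_b` (vector or matrix, NA where either map is masked).
#' @export
fe_difference <- function(a, b) {
  stopifnot(class(a)[1] == class(b)[1])
  if (inherits(a, "fe_profile")) {
    if (!isTRUE(all.equal(a$bin_edges, b$bin_edges))) {
      stop("bin edges differ; difference maps need shared bins",
           call. = FALSE)
    }
  } else {
    if (!isTRUE(all.equal(a$bin_edges_x, b$bin_edges_x)) ||
        !isTRUE(all.equal(a$bin_edges_y, b$bin_edges_y))) {
      stop("bin edges differ; difference maps need shared bins",
           call. = FALSE)
    }
  }
  a$G - b$G
}

# two-sample KS statistic with the location of the maximal ECDF distance;
# ECDF differences are evaluated after each full tie group
.ks_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  ord <- order(z)
  zs <- z[ord]
  cum <- cumsum(ifelse(ord <= nx, 1 / nx, -1 / ny))
  keep <- c(diff(zs) != 0, TRUE)
  cum <- cum[keep]
  zs <- zs[keep]
  i <- which.max(abs(cum))
  list(stat = abs(cum[i]), location = zs[i])
}

#' Replica-based Kolmogorov--Smirnov comparison of two groups
#'
#' Correlated MD samples break the nominal KS-test null distribution, so
#' instead of p-values the empirical distribution of the two-sample KS
#' statistic itself is built: within-group values from every unordered pair
#' of replicas inside each group, between-group values from every cross
#' pair. If the two groups sample the same equilibrium distribution, the
#' between-group values fall inside the within-group spread. The overlap
#' summary is the fraction of between-group statistics below the 95th
#' percentile of the pooled within-group distribution.
#'
#' @param group_a,group_b lists (>= 2 each) of numeric vectors or
#'   [cv_series()] replicas
#' @return Object of class `ks_comparison`: `within_a`, `within_b`,
#'   `between` (data.frames with `stat` and `location`), `overlap`
#'   (fraction in `[0, 1]`), `threshold95`.
#' @export
ks_replica_comparison <- function(group_a, group_b) {
  unpack <- function(g) lapply(g, function(r) {
    if (inherits(r, "cv_series")) r$values else as.numeric(r)
  })
  A <- unpack(group_a)
  B <- unpack(group_b)
  if (length(A) < 2L || length(B) < 2L) {
    stop("insufficient replicas: need >= 2 per group", call. = FALSE)
  }
  pair_stats <- function(reps) {
    idx <- utils::combn(length(reps), 2L)
    out <- apply(idx, 2L, function(ij) {
      s <- .ks_stat(reps[[ij[1]]], reps[[ij[2]]])
      c(s$stat, s$location)
    })
    data.frame(stat = out[1, ], location = out[2, ])
  }
  cross_stats <- function(ra, rb) {
    grid <- expand.grid(i = seq_along(ra), j = seq_along(rb))
    out <- mapply(function(i, j) {
      s <- .ks_stat(ra[[i]], rb[[j]])
      c(s$stat, s$location)
    }, grid$i, grid$j)
    data.frame(stat = out[1, ], location = out[2, ])
  }
  within_a <- pair_stats(A)
  within_b <- pair_stats(B)
  between <- cross_stats(A, B)
  thr <- stats::quantile(c(within_a$stat, within_b$stat), 0.95,
                         names = FALSE)
  structure(
    list(within_a = within_a, within_b = within_b, between = between,
         overlap = mean(between$stat <= thr), threshold95 = thr),
    class = "ks_comparison"
  )
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf(
    "KS replica comparison: within med %.3g/%.3g, between med %.3g, overlap %.2f\n",
    stats::median(x$within_a$stat), stats::median(x$within_b$stat),
    stats::median(x$between$stat), x$overlap))
  invisible(x)
}
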