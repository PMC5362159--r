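# MCMC mixing and accuracy diagnostics: autocorrelation-based effective
# sample size with the 0.1 truncation rule, Gaussian kernel density
# estimation, Kullback-Leibler divergence between gridded densities, a
# particle-filter-averaged reference posterior on a one-dimensional
# parameter slice, and KDE mode-occupancy analysis of traces.

#' Sample autocorrelation at a given lag
#'
#' Standard sample autocorrelation normalised by the lag-0 variance
#' (`alpha(0) = 1`), as computed by [stats::acf()].
#'
#' @param samples numeric vector.
#' @param lag lag `k < length(samples)`.
#' @export
autocorrelation <- function(samples, lag) {
  if (lag >= length(samples)) stop("'lag' must be smaller than the series length")
  if (stats::var(samples) == 0)
    stop("autocorrelation is undefined for a constant series")
  as.numeric(stats::acf(samples, lag.max = lag, plot = FALSE,
                        demean = TRUE)$acf[lag + 1L])
}

#' Effective sample size from truncated autocorrelations
#'
#' Computes `ESS = N / (1 + 2 * sum_{k=1}^{K} alpha(k))`, where the sum is
#' truncated at the last lag before the autocorrelation drops below 0.1
#' (a common variance-reduction rule for the estimator).
#'
#' @param samples numeric vector of post-burn-in MCMC samples.
#' @param max_lag largest lag considered when searching for the truncation
#'   point (capped at `length(samples) - 1`).
#' @return An object of class `"ess_report"`: `n`, `autocorrelations` (lags
#'   1..), `truncation_lag` (first lag with `alpha < 0.1`) and `ess`.
#' @export
effective_sample_size <- function(samples, max_lag = 2000L) {
  n <- length(samples)
  if (stats::var(samples) == 0)
    stop("effective sample size is undefined for a constant series")
  max_lag <- min(as.integer(max_lag), n - 1L)
  alpha <- as.numeric(stats::acf(samples, lag.max = max_lag, plot = FALSE,
                                 demean = TRUE)$acf)[-1L]
  rep <- ess_from_autocorr(alpha, n)
  structure(c(rep, list(autocorrelations = alpha)), class = "ess_report")
}

#' Effective sample size from a given autocorrelation sequence
#'
#' The truncation-and-sum rule of [effective_sample_size()] applied to an
#' explicit autocorrelation sequence `alpha(1), alpha(2), ...`.
#'
#' @param alpha autocorrelations at lags 1, 2, ...
#' @param n number of samples.
#' @return List with `n`, `truncation_lag` and `ess`.
#' @export
ess_from_autocorr <- function(alpha, n) {
  k0 <- which(alpha < 0.1)[1L]  # first lag below the 0.1 threshold
  K <- if (is.na(k0)) length(alpha) else k0 - 1L
  list(n = n, truncation_lag = if (is.na(k0)) NA_integer_ else as.integer(k0),
       ess = n / (1 + 2 * sum(alpha[seq_len(K)])))
}

#' @export
print.ess_report <- function(x, ...) {
  cat(sprintf("ESS = %.1f of %d samples (truncated at lag %s)\n",
              x$ess, x$n,
              if (is.na(x$truncation_lag)) "cap" else x$truncation_lag))
  invisible(x)
}

#' Gaussian kernel density estimate on a grid
#'
#' Gaussian-kernel KDE with bandwidth equal to the kernel standard
#' deviation. The default grid spans the sample range plus four bandwidths
#' on each side with 2048 points. For moderate problem sizes the estimate is
#' computed exactly; large ones go through the binned FFT estimator of
#' [stats::density()] (equally spaced grids only).
#'
#' @param samples numeric vector (at least 2 values).
#' @param bandwidth Gaussian kernel standard deviation (default 0.85, the
#'   case-study setting).
#' @param grid optional evaluation grid (increasing).
#' @param n_grid number of points of the automatic grid.
#' @return An object of class `"density_estimate"`: `grid`, `density`,
#'   `bandwidth`.
#' @export
kde_density <- function(samples, bandwidth = 0.85, grid = NULL,
                        n_grid = 2048L) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  if (is.null(grid))
    grid <- seq(min(samples) - 4 * bandwidth, max(samples) + 4 * bandwidth,
                length.out = n_grid)
  if (is.unsorted(grid)) stop("'grid' must be increasing")
  equispaced <- length(grid) > 1L &&
    max(abs(diff(grid) - (grid[2L] - grid[1L]))) < 1e-8 * abs(grid[2L] - grid[1L])
  exact_budget <- 2^24
  if (length(samples) * length(grid) <= exact_budget) {
    dens <- kde_exact(samples, bandwidth, grid)
  } else if (equispaced) {
    d <- stats::density(samples, bw = bandwidth, kernel = "gaussian",
                        from = grid[1L], to = grid[length(grid)],
                        n = length(grid))
    dens <- d$y
  } else {
    d <- stats::density(samples, bw = bandwidth, kernel = "gaussian",
                        from = min(grid), to = max(grid), n = 4096L)
    dens <- stats::approx(d$x, d$y, xout = grid, rule = 2L)$y
  }
  structure(list(grid = grid, density = dens, bandwidth = bandwidth),
            class = "density_estimate")
}

# Exact KDE evaluated in sample chunks to bound memory.
kde_exact <- function(samples, bandwidth, grid) {
  dens <- numeric(length(grid))
  chunk <- max(1L, floor(2^22 / length(grid)))
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + chunk - 1L, length(samples))
    dens <- dens + colSums(stats::dnorm(outer(samples[i:j], grid, "-"),
                                        sd = bandwidth))
    i <- j + 1L
  }
  dens / length(samples)
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density estimate on %d grid points in [%.4g, %.4g]",
              length(x$grid), x$grid[1L], x$grid[length(x$grid)]))
  if (is.finite(x$bandwidth))
    cat(sprintf(" (Gaussian kernel, bandwidth %.3g)", x$bandwidth))
  cat("\n")
  invisible(x)
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' Kullback-Leibler divergence between two gridded densities
#'
#' `KLD(p || q) = integral p log(p / q)`, computed by trapezoidal quadrature
#' on the shared grid. Both densities are renormalised on the grid first;
#' `q` is floored at a tiny epsilon where it vanishes so the ratio stays
#' finite. Nonnegative up to quadrature error.
#'
#' @param p reference density (a `"density_estimate"` or a list with `grid`
#'   and `density`).
#' @param q approximating density on the same grid.
#' @param eps floor applied to `q`.
#' @return Scalar divergence (nats).
#' @export
kld <- function(p, q, eps = 1e-12) {
  if (length(p$grid) != length(q$grid) ||
      max(abs(p$grid - q$grid)) > 1e-10 * max(1, abs(p$grid)))
    stop("'p' and 'q' must share the same grid")
  g <- p$grid
  pd <- p$density / trapezoid(g, p$density)
  qd <- q$density / trapezoid(g, q$density)
  qd[qd <= 0] <- eps
  integrand <- ifelse(pd > 0, pd * log(pd / qd), 0)
  trapezoid(g, integrand)
}

#' Reference posterior on a one-dimensional parameter slice
#'
#' Builds a gridded reference density for one parameter component, holding
#' the remaining components fixed: at each grid point the likelihood is
#' estimated by averaging `exp(log-likelihood)` over independent particle
#' filter replicates (unbiasedness makes the average converge to the exact
#' likelihood), multiplied by the prior and normalised on the grid. This is
#' a conditional-slice reference, not a marginal posterior.
#'
#' @param model an [ssm_model()].
#' @param grid grid of values for the varied component.
#' @param theta_fixed full parameter vector supplying the fixed components.
#' @param component index of the component swept along `grid`.
#' @param prior a [gamma_prior()] or log-density function.
#' @param particles particles per filter run.
#' @param replicates independent filter runs averaged per grid point.
#' @param resample resampling scheme passed to [particle_filter()].
#' @return A `"density_estimate"` on `grid` (bandwidth `NA`).
#' @export
reference_posterior_grid <- function(model, grid, theta_fixed, component = 1L,
                                     prior, particles = 256, replicates = 20,
                                     resample = "rsr") {
  lp <- as_log_prior(prior)
  log_post <- vapply(grid, function(g) {
    theta <- theta_fixed
    theta[component] <- g
    lpg <- lp$log_density(theta)
    if (!is.finite(lpg)) return(-Inf)
    lls <- vapply(seq_len(replicates), function(r)
      particle_filter(model, theta, particles, resample,
                      save_history = FALSE)$log_likelihood,
      numeric(1))
    log_mean_exp(lls) + lpg
  }, numeric(1))
  if (!any(is.finite(log_post)))
    stop("all grid points produced degenerate likelihood estimates")
  dens <- exp(log_post - max(log_post[is.finite(log_post)]))
  dens <- dens / trapezoid(grid, dens)
  structure(list(grid = grid, density = dens, bandwidth = NA_real_),
            class = "density_estimate")
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(mean(exp(x - m)))
}

#' Locate high-occupancy posterior modes in a trace
#'
#' Finds the local maxima of the Gaussian KDE of the samples, assigns each
#' sample to its nearest peak and reports peaks holding at least
#' `min_occupancy` of the samples, sorted by location.
#'
#' @param samples numeric vector of post-burn-in samples.
#' @param bandwidth KDE bandwidth (default 0.85).
#' @param min_occupancy minimum sample fraction for a reported mode.
#' @return Data frame with columns `location` and `occupancy`.
#' @export
mode_occupancy <- function(samples, bandwidth = 0.85, min_occupancy = 0.05) {
  if (length(samples) < 1L) stop("empty sample vector")
  if (length(unique(samples)) == 1L)
    return(data.frame(location = samples[1L], occupancy = 1))
  kd <- kde_density(samples, bandwidth = bandwidth)
  y <- kd$density
  m <- length(y)
  is_peak <- c(FALSE, y[2:(m - 1L)] >= y[1:(m - 2L)] &
                 y[2:(m - 1L)] > y[3:m], FALSE)
  peaks <- kd$grid[is_peak]
  if (length(peaks) == 0L) peaks <- kd$grid[which.max(y)]
  nearest <- vapply(samples, function(s) which.min(abs(peaks - s)), integer(1))
  occ <- tabulate(nearest, nbins = length(peaks)) / length(samples)
  keep <- occ >= min_occupancy
  out <- data.frame(location = peaks[keep], occupancy = occ[keep])
  out[order(out$location), , drop = FALSE]
}
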