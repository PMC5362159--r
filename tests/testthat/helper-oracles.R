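# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Kalman filter gives the exact likelihood of
# the linear-Gaussian model, direct formula evaluation gives Gamma
# log-densities, and small toy models give exact-likelihood targets for the
# samplers.

# Exact log-likelihood of the linear-Gaussian SSM
#   X1 ~ N(0, 1), X_t ~ N(X_{t-1}, q), Y_t ~ N(X_t, r)
# via the Kalman filter recursions.
kalman_loglik <- function(y, q, r) {
  m <- 0; V <- 1  # predictive mean/variance of X_1
  ll <- 0
  for (t in seq_along(y)) {
    S <- V + r
    ll <- ll + dnorm(y[t], m, sqrt(S), log = TRUE)
    K <- V / S
    m <- m + K * (y[t] - m)
    V <- V - K * V
    m <- m; V <- V + q  # predict next step
  }
  ll
}

# Direct Gamma log-density (shape/scale), written out rather than calling
# dgamma so it is independent of the implementation under test.
gamma_logpdf_direct <- function(x, shape, scale) {
  (shape - 1) * log(x) - x / scale - lgamma(shape) - shape * log(scale)
}

# Exact-likelihood "SSM": one step, deterministic particles, observation
# weight equal to a supplied log-likelihood function of theta. The particle
# filter then returns log_lik_fun(theta) exactly for any particle count,
# i.e. a zero-variance pseudo-marginal estimate.
exact_likelihood_model <- function(log_lik_fun, n_theta = 1L) {
  ssm_model(
    n_steps = 1L,
    sample_initial = function(n, theta) rep(0, n),
    sample_transition = function(x, t, theta) x,
    observation_log_weight = function(x, t, theta)
      rep(log_lik_fun(theta), length(x)),
    n_theta = n_theta,
    name = "exact-likelihood")
}

# Equal-weight two-component Normal mixture target (modes at 0 and 10).
bimodal_log_density <- function(theta) {
  log(0.5 * dnorm(theta[1], 0, 1) + 0.5 * dnorm(theta[1], 10, 1))
}

flat_log_prior <- function(theta) 0

# Model with unit observation weights everywhere (flat likelihood).
flat_weight_model <- function(n_steps, n_theta = 1L) {
  ssm_model(
    n_steps = n_steps,
    sample_initial = function(n, theta) rnorm(n),
    sample_transition = function(x, t, theta) rnorm(length(x), x, 1),
    observation_log_weight = function(x, t, theta) rep(0, length(x)),
    n_theta = n_theta,
    name = "flat-likelihood")
}

# Total-variation distance between a sample and a gridded density, on
# equal-width bins spanning the grid.
tv_sample_vs_grid <- function(samples, grid, density, n_bins = 20) {
  breaks <- seq(min(grid), max(grid), length.out = n_bins + 1)
  samples <- pmin(pmax(samples, breaks[1]), breaks[n_bins + 1])
  emp <- hist(samples, breaks = breaks, plot = FALSE)$counts / length(samples)
  dx <- diff(grid[1:2])
  dens_mass <- vapply(seq_len(n_bins), function(b) {
    sel <- grid >= breaks[b] & grid < breaks[b + 1]
    sum(density[sel]) * dx
  }, numeric(1))
  dens_mass <- dens_mass / sum(dens_mass)
  0.5 * sum(abs(emp - dens_mass))
}
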