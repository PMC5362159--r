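# One-dimensional linear-Gaussian state-space model.
#
# X_1 ~ Normal(0, 1), X_t ~ Normal(X_{t-1}, q), Y_t ~ Normal(X_t, r).
# Its likelihood is available exactly through the Kalman filter, which makes
# it the validation model of choice for the particle filter (unbiasedness of
# the likelihood estimate) and for pseudo-marginal correctness checks.

#' Linear-Gaussian state-space model
#'
#' Random-walk state with innovation variance `q = theta[1]`; Gaussian
#' observations with variance `obs_var` (fixed, the default 1) or, when
#' `obs_var = NULL`, estimated as `theta[2]`. The observation log-weight is
#' the exact Gaussian log-density (deterministic weights).
#'
#' @param y numeric vector of observations (defines `T`).
#' @param obs_var known observation variance, or `NULL` to treat it as the
#'   second parameter component.
#' @return An [ssm_model()].
#' @export
linear_gaussian_ssm <- function(y, obs_var = 1) {
  y <- as.numeric(y)
  fixed_r <- !is.null(obs_var)
  get_r <- if (fixed_r) function(theta) obs_var else function(theta) theta[2L]
  ssm_model(
    n_steps = length(y),
    sample_initial = function(n, theta) stats::rnorm(n, 0, 1),
    sample_transition = function(x, t, theta)
      stats::rnorm(length(x), x, sqrt(theta[1L])),
    observation_log_weight = function(x, t, theta)
      stats::dnorm(y[t], x, sqrt(get_r(theta)), log = TRUE),
    n_theta = if (fixed_r) 1L else 2L,
    theta_names = if (fixed_r) "state_var" else c("state_var", "obs_var"),
    name = "linear-gaussian")
}

#' Simulate from the linear-Gaussian model
#'
#' @param n_steps number of time steps.
#' @param state_var state innovation variance `q`.
#' @param obs_var observation variance `r`.
#' @param seed optional seed (ambient RNG left untouched when supplied).
#' @return List with `x` (states) and `y` (observations).
#' @export
simulate_linear_gaussian <- function(n_steps, state_var = 0.5, obs_var = 1,
                                     seed = NULL) {
  with_local_seed(seed, {
    x <- numeric(n_steps)
    x[1L] <- stats::rnorm(1L, 0, 1)
    if (n_steps > 1L)
      for (t in 2:n_steps)
        x[t] <- stats::rnorm(1L, x[t - 1L], sqrt(state_var))
    y <- stats::rnorm(n_steps, x, sqrt(obs_var))
    list(x = x, y = y)
  })
}
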