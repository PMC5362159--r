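# State-space model contract and parameter priors.
#
# An SSM is defined by an initial density e(X1), a transition density
# f(X_t | X_{t-1}, theta) and an observation density g(y_t | X_t, theta).
# The particle filter and the samplers only touch models through the three
# closures below, all vectorised over particles, so any model satisfying the
# contract can be plugged in.

#' Define a state-space model
#'
#' Constructs the model object consumed by [particle_filter()], [pmcmc()] and
#' [ppmcmc()]. The three closures are vectorised over particles and consume
#' the ambient RNG stream (the samplers route them through dedicated
#' substreams).
#'
#' @param n_steps number of time steps `T >= 1`.
#' @param sample_initial `function(n_particles, theta)` returning `n_particles`
#'   draws from the initial density `e(X1)`.
#' @param sample_transition `function(x, t, theta)` returning one transition
#'   draw per entry of `x`, for time step `t >= 2`.
#' @param observation_log_weight `function(x, t, theta)` returning per-particle
#'   log-weights whose exponential is an unbiased (possibly stochastic)
#'   estimate of the observation density `g(y_t | x, theta)`.
#' @param n_theta dimension of the parameter vector the closures expect.
#' @param theta_names optional character names for the parameter components.
#' @param name short model label used in printing and metadata.
#' @return An object of class `"ssm_model"`.
#' @examples
#' m <- ssm_model(
#'   n_steps = 3,
#'   sample_initial = function(n, theta) rnorm(n),
#'   sample_transition = function(x, t, theta) rnorm(length(x), x, sqrt(theta[1])),
#'   observation_log_weight = function(x, t, theta) dnorm(0, x, 1, log = TRUE),
#'   n_theta = 1
#' )
#' @export
ssm_model <- function(n_steps, sample_initial, sample_transition,
                      observation_log_weight, n_theta = 1L,
                      theta_names = NULL, name = "ssm") {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be at least 1")
  stopifnot(is.function(sample_initial), is.function(sample_transition),
            is.function(observation_log_weight))
  if (!is.null(theta_names) && length(theta_names) != n_theta)
    stop("'theta_names' must have one entry per parameter component")
  structure(
    list(n_steps = n_steps,
         sample_initial = sample_initial,
         sample_transition = sample_transition,
         observation_log_weight = observation_log_weight,
         n_theta = as.integer(n_theta),
         theta_names = theta_names,
         name = name),
    class = "ssm_model")
}

#' @export
print.ssm_model <- function(x, ...) {
  cat("State-space model:", x$name, "\n")
  cat("  time steps:", x$n_steps, "  parameters:", x$n_theta, "\n")
  invisible(x)
}

#' Independent Gamma priors for variance components
#'
#' One (shape, scale) pair per parameter component; the joint prior is the
#' product of independent Gamma densities. Support is the positive orthant:
#' the log-density is `-Inf` whenever any component is non-positive, which is
#' how out-of-support random-walk proposals are rejected.
#'
#' @param shape,scale positive numeric vectors of equal length.
#' @return An object of class `"gamma_prior"`.
#' @seealso [evaluate_log_prior()], [methylation_prior()]
#' @export
gamma_prior <- function(shape, scale) {
  shape <- as.numeric(shape); scale <- as.numeric(scale)
  if (length(shape) != length(scale))
    stop("'shape' and 'scale' must have the same length")
  if (any(shape <= 0) || any(scale <= 0))
    stop("Gamma shape and scale parameters must be positive")
  structure(list(shape = shape, scale = scale, n_theta = length(shape)),
            class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat("Independent Gamma prior (shape, scale):\n")
  for (i in seq_along(x$shape))
    cat(sprintf("  component %d: (%g, %g)\n", i, x$shape[i], x$scale[i]))
  invisible(x)
}

#' Log prior density of a parameter vector
#'
#' Sum of independent Gamma log-densities; returns `-Inf` for any vector with
#' a non-positive component (outside the prior support).
#'
#' @param theta numeric parameter vector.
#' @param prior a [gamma_prior()].
#' @return Log prior density (scalar; `-Inf` outside the support).
#' @examples
#' evaluate_log_prior(1, gamma_prior(1, 1))  # Exponential(1) at 1: -1
#' @export
evaluate_log_prior <- function(theta, prior) {
  stopifnot(inherits(prior, "gamma_prior"))
  if (length(theta) != prior$n_theta)
    stop(sprintf("parameter vector has length %d but the prior expects %d components",
                 length(theta), prior$n_theta))
  if (any(theta <= 0)) return(-Inf)
  sum(stats::dgamma(theta, shape = prior$shape, scale = prior$scale, log = TRUE))
}

# Normalise a prior specification into a log-density function plus an
# optional sampler used for default initialisation.
as_log_prior <- function(prior) {
  if (inherits(prior, "gamma_prior")) {
    list(log_density = function(theta) evaluate_log_prior(theta, prior),
         sample = function() stats::rgamma(prior$n_theta, shape = prior$shape,
                                           scale = prior$scale),
         n_theta = prior$n_theta)
  } else if (is.function(prior)) {
    list(log_density = prior, sample = NULL, n_theta = NA_integer_)
  } else {
    stop("'prior' must be a gamma_prior object or a log-density function")
  }
}
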