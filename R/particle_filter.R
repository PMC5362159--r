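# Bootstrap particle filter with log-domain weights, max-log-weight
# renormalisation and residual systematic resampling (RSR).
#
# The filter resamples at the start of every step t >= 2 (never before t = 1),
# propagates particles through the transition density and weights them with
# the observation density. exp(log_likelihood) is an unbiased estimate of the
# marginal likelihood l(y_{1:T} | theta), the property pseudo-marginal MCMC
# rests on.

#' Shift log-weights by their maximum
#'
#' Renormalises a log-weight vector by its maximum so that exponentiation is
#' overflow/underflow-safe: the largest resulting weight is exactly 1.
#'
#' @param logw numeric vector of log-weights (at least one finite entry).
#' @return List with `max_logw` and `weights` (`exp(logw - max_logw)`).
#' @export
normalize_log_weights <- function(logw) {
  m <- max(logw)
  if (!is.finite(m))
    stop(particle_degeneracy_condition())
  list(max_logw = m, weights = exp(logw - m))
}

particle_degeneracy_condition <- function() {
  errorCondition("particle degeneracy: all log-weights are -Inf (zero likelihood estimate)",
                 class = "particle_degeneracy")
}

#' Per-step log-likelihood contribution
#'
#' Log of the mean weight, `log((1/P) * sum(exp(logw)))`, computed stably via
#' max-log-weight renormalisation. Summed over time steps this is the particle
#' filter's log-likelihood estimate.
#'
#' @inheritParams normalize_log_weights
#' @return Scalar log mean weight.
#' @export
step_log_likelihood <- function(logw) {
  nw <- normalize_log_weights(logw)
  nw$max_logw + log(mean(nw$weights))
}

#' Residual systematic resampling
#'
#' Deterministic given the weights and a single uniform draw
#' `u` in `[0, 1/P)`: replication counts follow the one-pass recurrence
#' `r_m = floor((w_m - u) * P) + 1`, `u <- u + r_m / P - w_m`. Counts sum to
#' `P` and have expectation `P * w_m` over the uniform draw.
#'
#' @param weights normalised weights summing to 1.
#' @param u single uniform draw in `[0, 1/P)`.
#' @return Integer vector of replication counts summing to `length(weights)`.
#' @export
rsr_resample <- function(weights, u) {
  P <- length(weights)
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (u < 0 || u >= 1 / P) stop("'u' must lie in [0, 1/P)")
  .rsr_resample_cpp(as.numeric(weights), u)
}

#' Expand replication counts into sorted ancestor indices
#'
#' Expansion by definition: index `p` appears `counts[p]` times, in
#' nondecreasing order. Inside the filter the counts come from
#' [rsr_resample()] and always sum to the particle count (asserted there).
#'
#' @param counts nonnegative integer replication counts.
#' @return Integer vector of parent indices in nondecreasing order.
#' @export
counts_to_ancestors <- function(counts) {
  if (any(counts < 0)) stop("replication counts must be nonnegative")
  rep.int(seq_along(counts), counts)
}

# Multinomial alternative to RSR (cross-checking option).
multinomial_ancestors <- function(weights) {
  P <- length(weights)
  sort(sample.int(P, P, replace = TRUE, prob = weights))
}

#' Run the bootstrap particle filter
#'
#' Executes, per time step: resample (RSR with a fresh uniform per step, or
#' multinomial), propagate through the transition density, weight with the
#' observation density. Accumulates the unbiased log-likelihood estimate
#' `sum_t log((1/P) sum_p W_t^p)` and, when `save_history = TRUE`, draws a
#' state path by selecting a terminal particle with probability proportional
#' to the final-step weights and tracing its ancestry.
#'
#' If all particles receive zero weight at some step the filter stops with a
#' `log_likelihood` of `-Inf` (the candidate is then certain to be rejected
#' by the samplers).
#'
#' @param model an [ssm_model()].
#' @param theta numeric parameter vector passed to the model closures.
#' @param particles number of particles `P >= 2`.
#' @param resample `"rsr"` (default) or `"multinomial"`.
#' @param save_history keep per-step particles and ancestry and return a
#'   sampled path; turn off inside long MCMC runs where only the likelihood
#'   estimate is needed.
#' @return An object of class `"pf_result"`: `log_likelihood`,
#'   `per_step_log_means` (length `T`), `path` (length `T`, or `NULL`),
#'   `degenerate` flag.
#' @examples
#' m <- linear_gaussian_ssm(y = c(0.4, -0.2, 0.1))
#' particle_filter(m, theta = 0.5, particles = 64)$log_likelihood
#' @export
particle_filter <- function(model, theta, particles = 256,
                            resample = c("rsr", "multinomial"),
                            save_history = TRUE) {
  stopifnot(inherits(model, "ssm_model"))
  resample <- match.arg(resample)
  P <- as.integer(particles)
  if (P < 2L) stop("'particles' must be at least 2")
  TT <- model$n_steps

  # models with a compiled filter use it whenever its restrictions
  # (RSR resampling, no stored history) apply
  if (!save_history && resample == "rsr" && !is.null(model$native_filter))
    return(model$native_filter(theta, P))

  per_step <- rep(NA_real_, TT)
  if (save_history) {
    X <- matrix(NA_real_, P, TT)
    A <- matrix(NA_integer_, P, TT)
    A[, 1L] <- seq_len(P)
  }

  x <- model$sample_initial(P, theta)
  logw <- model$observation_log_weight(x, 1L, theta)
  degenerate <- !any(is.finite(logw))
  if (!degenerate) {
    per_step[1L] <- step_log_likelihood(logw)
    if (save_history) X[, 1L] <- x
  }

  t <- 2L
  while (!degenerate && t <= TT) {
    nw <- normalize_log_weights(logw)
    w <- nw$weights / sum(nw$weights)
    anc <- if (resample == "rsr") {
      counts_to_ancestors(rsr_resample(w, stats::runif(1L, 0, 1 / P)))
    } else {
      multinomial_ancestors(w)
    }
    x <- model$sample_transition(x[anc], t, theta)
    logw <- model$observation_log_weight(x, t, theta)
    if (!any(is.finite(logw))) {
      degenerate <- TRUE
      break
    }
    per_step[t] <- step_log_likelihood(logw)
    if (save_history) {
      X[, t] <- x
      A[, t] <- anc
    }
    t <- t + 1L
  }

  if (degenerate) {
    return(structure(list(log_likelihood = -Inf, per_step_log_means = per_step,
                          path = NULL, particles = P, n_steps = TT,
                          degenerate = TRUE),
                     class = "pf_result"))
  }

  path <- NULL
  if (save_history) {
    wT <- normalize_log_weights(logw)$weights
    k <- sample.int(P, 1L, prob = wT)
    path <- numeric(TT)
    idx <- k
    for (s in TT:1L) {
      path[s] <- X[idx, s]
      idx <- A[idx, s]
    }
  }

  structure(list(log_likelihood = sum(per_step), per_step_log_means = per_step,
                 path = path, particles = P, n_steps = TT, degenerate = FALSE),
            class = "pf_result")
}

#' @export
print.pf_result <- function(x, ...) {
  cat("Bootstrap particle filter result\n")
  cat(sprintf("  particles: %d   time steps: %d\n", x$particles, x$n_steps))
  cat(sprintf("  log-likelihood estimate: %.6g%s\n", x$log_likelihood,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
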