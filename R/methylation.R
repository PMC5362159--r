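# Hierarchical state-space models of DNA methylation profiles.
#
# The hidden state X_t is the logit of the methylation probability at DNA
# base t. Single-tissue samples follow a Gaussian random walk whose variance
# scales with the physical gap between bases; mixed-tissue samples follow an
# equal-weight two-component mixture walk (two inter-base dependence scales),
# which makes the two walk variances exchangeable and the posterior bimodal.
# Observations are per-replicate binomial counts of successful bisulfite
# tests, with a logit-normal random effect linking each replicate's
# methylation probability to the shared hidden state.

#' Sample DNA base positions with uniform gaps
#'
#' `delta_1 = 1`; inter-position gaps are uniform random integers in
#' `[1, 100]`, so positions are strictly increasing and every transition
#' variance is positive.
#'
#' @param n_positions number of bases `T >= 1`.
#' @return Integer vector of strictly increasing base-pair coordinates.
#' @export
methylation_positions <- function(n_positions) {
  n_positions <- as.integer(n_positions)
  if (n_positions < 1L) stop("'n_positions' must be at least 1")
  if (n_positions == 1L) return(1L)
  cumsum(c(1L, sample.int(100L, n_positions - 1L, replace = TRUE)))
}

#' Single-tissue transition draw
#'
#' `X_t ~ Normal(x_prev, sigma1_sq * gap)`: the walk variance scales linearly
#' with the physical gap between neighbouring bases.
#'
#' @param x_prev previous state(s) (vectorised over particles).
#' @param sigma1_sq walk variance per unit gap (squared logit-probability).
#' @param gap positive integer base-pair gap `delta_t - delta_{t-1}`.
#' @export
transition_single <- function(x_prev, sigma1_sq, gap) {
  stats::rnorm(length(x_prev), x_prev, sqrt(sigma1_sq * gap))
}

#' Two-component mixture transition draw (multi-tissue)
#'
#' With probability `weight` draw from `Normal(x_prev, sigma1_sq * gap)`,
#' otherwise from `Normal(x_prev, sigma2_sq * gap)`. The equal-weight default
#' makes the two variances exchangeable, which is what produces the two
#' label-switching posterior modes.
#'
#' @inheritParams transition_single
#' @param sigma2_sq second component's walk variance per unit gap.
#' @param weight mixture weight of the first component (fixed at 0.5 in the
#'   case studies).
#' @export
transition_mixture <- function(x_prev, sigma1_sq, sigma2_sq, gap,
                               weight = 0.5) {
  n <- length(x_prev)
  comp1 <- stats::runif(n) < weight
  v <- ifelse(comp1, sigma1_sq, sigma2_sq) * gap
  stats::rnorm(n, x_prev, sqrt(v))
}

#' Random-weight observation log-weight for one base
#'
#' For each replicate `k`, draws the logit-normal random effect
#' `logit(p_k) ~ Normal(x, beta_sq)` and returns
#' `sum_k log Binomial(y_k; n_k, p_k)`. The exponential is an unbiased
#' single-sample estimate of the marginal (random-effects-integrated)
#' observation density, so the particle filter built on it remains an
#' unbiased likelihood estimator (random-weight particle filter).
#'
#' @param x hidden state value(s), vectorised over particles.
#' @param y,n integer vectors of successes and trials, one entry per
#'   replicate (`0 <= y <= n`).
#' @param beta_sq between-replicate variance; 0 is allowed as a degenerate
#'   case (no random effect).
#' @return Per-particle log-weights (length of `x`).
#' @export
replicate_log_weight <- function(x, y, n, beta_sq) {
  P <- length(x)
  K <- length(y)
  stopifnot(length(n) == K, all(y >= 0), all(y <= n))
  # P x K matrix of replicate logit draws in one call
  z <- stats::rnorm(P * K, mean = rep(x, times = K), sd = sqrt(beta_sq))
  p <- stats::plogis(z)
  lw <- stats::dbinom(rep(y, each = P), rep(n, each = P), p, log = TRUE)
  .rowSums(lw, P, K)
}

#' Gamma priors for the methylation variance components
#'
#' Single tissue: shapes (1.2, 1.0) and scales (100, 100) for
#' `(sigma1_sq, beta_sq)`. Multi tissue: shapes (1.2, 1.2, 1.0) and scales
#' (100, 100, 100) for `(sigma1_sq, sigma2_sq, beta_sq)`. Diffuse priors
#' whose support comfortably covers both walk-variance posterior modes.
#'
#' @param tissue `"single"` or `"multi"`.
#' @return A [gamma_prior()].
#' @export
methylation_prior <- function(tissue = c("single", "multi")) {
  tissue <- match.arg(tissue)
  if (tissue == "single") gamma_prior(shape = c(1.2, 1.0), scale = c(100, 100))
  else gamma_prior(shape = c(1.2, 1.2, 1.0), scale = c(100, 100, 100))
}

#' Tuned single-chain proposal covariance diagonals
#'
#' The manually tuned random-walk variances for the methylation case
#' studies: `(0.15, 0.008)` for the single-tissue model and
#' `(1.1, 1.1, 0.008)` for the multi-tissue model.
#'
#' @inheritParams methylation_prior
#' @export
methylation_proposal <- function(tissue = c("single", "multi")) {
  tissue <- match.arg(tissue)
  if (tissue == "single") c(0.15, 0.008) else c(1.1, 1.1, 0.008)
}

#' Tuned per-chain proposal diagonals for population runs (multi-tissue)
#'
#' Hotter chains target smoother distributions and need larger proposal
#' variances. Returns the first `n_chains` of the five tuned diagonals;
#' beyond five chains, covariances must be supplied explicitly.
#'
#' @param n_chains number of chains (1 to 5).
#' @return List of `n_chains` covariance diagonals.
#' @export
methylation_chain_proposals <- function(n_chains) {
  all5 <- list(c(1.1, 1.1, 0.008),
               c(2.0, 2.0, 0.015),
               c(3.9, 3.9, 0.025),
               c(5.8, 5.8, 0.030),
               c(9.0, 9.0, 0.050))
  if (n_chains < 1L || n_chains > 5L)
    stop("tuned proposal diagonals exist for 1 to 5 chains; supply your own otherwise")
  all5[seq_len(n_chains)]
}

default_methylation_theta <- function(tissue) {
  if (tissue == "single") c(sigma1_sq = 0.2, beta_sq = 0.02)
  else c(sigma1_sq = 0.2, sigma2_sq = 10.0, beta_sq = 0.02)
}

#' Simulate a synthetic methylation dataset
#'
#' Generates positions with uniform integer gaps in `[1, 100]`, a hidden
#' logit-probability walk started at `X_1 ~ Normal(0, 1)`, per-replicate
#' logit-normal random effects, trial counts uniform in `[1, 50]` and
#' binomial success counts. The generating walk and parameters are attached
#' as ground truth.
#'
#' @param n_positions number of DNA bases `T`.
#' @param theta generating parameter values; defaults to `(0.2, 0.02)` for
#'   single tissue and `(0.2, 10.0, 0.02)` for multi tissue.
#' @param tissue `"single"` (one-component walk) or `"multi"` (equal-weight
#'   two-component mixture walk).
#' @param n_replicates number of biological replicates (4 in the case
#'   studies).
#' @param seed optional seed; the ambient RNG state is left untouched when
#'   it is supplied.
#' @return An object of class `"methylation_data"`: `n_positions`, `delta`,
#'   integer matrices `y` and `n` (`T x n_replicates`), ground truth
#'   `x_true` and `theta_true`, and `tissue`.
#' @examples
#' d <- simulate_methylation(50, tissue = "multi", seed = 7)
#' d
#' @export
simulate_methylation <- function(n_positions, theta = NULL,
                                 tissue = c("single", "multi"),
                                 n_replicates = 4, seed = NULL) {
  tissue <- match.arg(tissue)
  if (is.null(theta)) theta <- default_methylation_theta(tissue)
  d_expect <- if (tissue == "single") 2L else 3L
  if (length(theta) != d_expect)
    stop(sprintf("'theta' must have %d components for tissue = \"%s\"",
                 d_expect, tissue))
  if (any(theta <= 0)) stop("all variance components must be positive")
  TT <- as.integer(n_positions)
  if (TT < 1L) stop("'n_positions' must be at least 1")
  K <- as.integer(n_replicates)

  with_local_seed(seed, {
    delta <- methylation_positions(TT)
    x <- numeric(TT)
    x[1L] <- stats::rnorm(1L, 0, 1)
    if (TT > 1L) {
      gaps <- diff(delta)
      for (t in 2:TT) {
        x[t] <- if (tissue == "single") {
          transition_single(x[t - 1L], theta[1L], gaps[t - 1L])
        } else {
          transition_mixture(x[t - 1L], theta[1L], theta[2L], gaps[t - 1L])
        }
      }
    }
    beta_sq <- theta[length(theta)]
    n <- matrix(sample.int(50L, TT * K, replace = TRUE), TT, K)
    p <- stats::plogis(stats::rnorm(TT * K, mean = rep(x, times = K),
                                    sd = sqrt(beta_sq)))
    y <- matrix(stats::rbinom(TT * K, as.vector(n), p), TT, K)

    structure(list(n_positions = TT, delta = delta, y = y, n = n,
                   x_true = x, theta_true = theta, tissue = tissue,
                   n_replicates = K, seed = seed),
              class = "methylation_data")
  })
}

#' @export
print.methylation_data <- function(x, ...) {
  cat(sprintf("Synthetic methylation dataset (%s-tissue)\n", x$tissue))
  cat(sprintf("  %d positions spanning [%d, %d] bp, %d replicates\n",
              x$n_positions, x$delta[1L], x$delta[x$n_positions],
              x$n_replicates))
  cat("  generating parameters:",
      paste(sprintf("%.3g", x$theta_true), collapse = ", "), "\n")
  invisible(x)
}

#' Build the methylation state-space model for a dataset
#'
#' Binds a methylation dataset to the corresponding [ssm_model()]:
#' logit-probability walk transition (single Gaussian or equal-weight
#' mixture), `X_1 ~ Normal(0, 1)` initial density and the random-weight
#' binomial observation weight of [replicate_log_weight()]. Replicate random
#' effects are drawn fresh per particle per step and are not part of the
#' persisted state path.
#'
#' @param data a `"methylation_data"` object or anything accepted by
#'   [read_methylation()].
#' @param tissue model family; defaults to the dataset's own tissue label.
#' @return An `ssm_model` with parameter vector `(sigma1_sq, beta_sq)`
#'   (single) or `(sigma1_sq, sigma2_sq, beta_sq)` (multi).
#' @export
methylation_ssm <- function(data, tissue = NULL) {
  stopifnot(inherits(data, "methylation_data"))
  if (is.null(tissue)) tissue <- data$tissue
  tissue <- match.arg(tissue, c("single", "multi"))
  gaps <- c(NA_integer_, diff(data$delta))
  y <- data$y; n <- data$n
  single <- tissue == "single"

  transition <- if (single) {
    function(x, t, theta) transition_single(x, theta[1L], gaps[t])
  } else {
    function(x, t, theta) transition_mixture(x, theta[1L], theta[2L], gaps[t])
  }
  beta_index <- if (single) 2L else 3L

  m <- ssm_model(
    n_steps = data$n_positions,
    sample_initial = function(n_particles, theta) stats::rnorm(n_particles, 0, 1),
    sample_transition = transition,
    observation_log_weight = function(x, t, theta)
      replicate_log_weight(x, y[t, ], n[t, ], theta[beta_index]),
    n_theta = if (single) 2L else 3L,
    theta_names = names(default_methylation_theta(tissue)),
    name = paste0("methylation-", tissue))
  m$tissue <- tissue

  # compiled fast path (RSR only, no stored path): same model, same RNG
  # stream, one C++ call per filter run
  storage.mode(y) <- "integer"; storage.mode(n) <- "integer"
  lch <- matrix(lchoose(as.vector(n), as.vector(y)), nrow(n), ncol(n))
  gaps_c <- gaps; gaps_c[1L] <- 0L
  m$native_filter <- function(theta, particles) {
    res <- .meth_pf_cpp(y, n, lch, gaps_c,
                        sigma1_sq = theta[1L],
                        sigma2_sq = if (single) theta[1L] else theta[2L],
                        mixture = !single, beta_sq = theta[beta_index],
                        P = as.integer(particles))
    structure(list(log_likelihood = res$log_likelihood,
                   per_step_log_means = res$per_step_log_means,
                   path = NULL, particles = as.integer(particles),
                   n_steps = data$n_positions, degenerate = res$degenerate),
              class = "pf_result")
  }
  class(m) <- c("methylation_ssm", class(m))
  m
}
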