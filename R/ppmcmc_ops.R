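# Elementary sampler operations: random-walk proposal, pseudo-marginal
# acceptance ratios (plain and tempered), temperature ladders and
# neighbouring-pair exchange moves. All of these are pure given their RNG
# input and are exercised directly by the samplers.

#' Gaussian random-walk proposal
#'
#' Adds independent zero-mean Gaussian noise with the given diagonal
#' covariance to the current parameter vector. The proposal is symmetric, so
#' its density ratio cancels from the Metropolis-Hastings acceptance ratio.
#' Components proposed outside the prior support are handled downstream by
#' the zero prior (no reflection or folding).
#'
#' @param theta current parameter vector.
#' @param cov_diag diagonal of the proposal covariance (variances,
#'   nonnegative; zero gives a degenerate point proposal).
#' @return Proposed parameter vector.
#' @export
propose_theta <- function(theta, cov_diag) {
  if (length(cov_diag) != length(theta))
    stop("'cov_diag' must have one entry per parameter component")
  if (any(cov_diag < 0)) stop("proposal variances must be nonnegative")
  theta + stats::rnorm(length(theta), 0, sqrt(cov_diag))
}

# Internal representation of one chain's current state. `path` may be NULL
# when state paths are not stored. `log_lik` is the pseudo-marginal estimate
# computed when `theta` was last accepted and is never recomputed.
chain_state <- function(theta, log_lik, log_prior, path = NULL) {
  list(theta = theta, log_lik = log_lik, log_prior = log_prior, path = path)
}

#' Tempered pseudo-marginal log acceptance ratio
#'
#' Log of the acceptance ratio for a chain at temperature `temp`:
#' `[log rho(theta*) + log l~(y|theta*)/temp] - [log rho(theta) + log l~(y|theta)/temp]`.
#' At `temp = 1` this is exactly the plain pseudo-marginal ratio. A proposed
#' state with `-Inf` log-prior or log-likelihood yields `-Inf` (certain
#' rejection); a current state with `-Inf` stored values yields `+Inf`
#' (certain acceptance of any valid candidate).
#'
#' @param current,proposed chain states: lists with elements `log_lik` and
#'   `log_prior`.
#' @param temp temperature, `>= 1`.
#' @return Log acceptance ratio; accept iff `log(U) < ratio`, `U ~ Unif(0,1)`.
#' @export
tempered_log_acceptance <- function(current, proposed, temp = 1) {
  if (temp < 1) stop("'temp' must be at least 1")
  if (!is.finite(proposed$log_prior) || !is.finite(proposed$log_lik))
    return(-Inf)
  if (!is.finite(current$log_prior) || !is.finite(current$log_lik))
    return(Inf)
  (proposed$log_prior + proposed$log_lik / temp) -
    (current$log_prior + current$log_lik / temp)
}

#' Pseudo-marginal log acceptance ratio (single untempered chain)
#'
#' The plain particle-MCMC ratio, i.e. [tempered_log_acceptance()] at
#' temperature 1.
#'
#' @inheritParams tempered_log_acceptance
#' @export
log_acceptance_ratio <- function(current, proposed) {
  tempered_log_acceptance(current, proposed, temp = 1)
}

#' Additive temperature ladder
#'
#' `(1, 1 + inc, 1 + 2*inc, ...)`; the cold chain always sits at temperature
#' 1 and targets the exact posterior.
#'
#' @param n_chains number of chains `M >= 1`.
#' @param increment additive step between consecutive temperatures (`> 0`).
#' @param t1 first temperature; must be 1.
#' @return Numeric vector of `n_chains` strictly increasing temperatures.
#' @examples
#' build_temperature_ladder(5)  # 1, 3.5, 6, 8.5, 11
#' @export
build_temperature_ladder <- function(n_chains, increment = 2.5, t1 = 1) {
  n_chains <- as.integer(n_chains)
  if (n_chains < 1L) stop("'n_chains' must be at least 1")
  if (t1 != 1) stop("the first temperature must be exactly 1")
  if (increment <= 0) stop("'increment' must be positive")
  t1 + increment * (seq_len(n_chains) - 1)
}

#' Exchange-move log acceptance ratio
#'
#' For neighbouring chains `q` and `r` with stored log-likelihood estimates
#' `logL_q`, `logL_r`:
#' `(logL_r - logL_q) * (1/temp_q - 1/temp_r)`. Only stored estimates enter;
#' no additional particle filter runs are required. Nonfinite inputs give
#' `-Inf`, except that identical temperatures always give 0.
#'
#' @param logL_q,logL_r stored log-likelihood estimates of the two chains.
#' @param temp_q,temp_r their temperatures (`>= 1`).
#' @return Log acceptance ratio of the swap.
#' @export
exchange_log_ratio <- function(logL_q, logL_r, temp_q, temp_r) {
  if (temp_q == temp_r) return(0)
  if (!is.finite(logL_q) || !is.finite(logL_r)) return(-Inf)
  (logL_r - logL_q) * (1 / temp_q - 1 / temp_r)
}

#' Rotating neighbouring-pair schedule for exchange moves
#'
#' Odd iterations (1-based) attempt pairs starting at chain 1:
#' `(1,2), (3,4), ...`; even iterations start at chain 2: `(2,3), (4,5), ...`.
#' Pairs within one iteration are disjoint.
#'
#' @param iteration 1-based iteration counter.
#' @param n_chains number of chains.
#' @return List of integer pairs `c(q, q + 1)` (possibly empty).
#' @export
select_exchange_pairs <- function(iteration, n_chains) {
  start <- if (iteration %% 2 == 1) 1L else 2L
  if (n_chains < start + 1L) return(list())
  firsts <- seq.int(start, n_chains - 1L, by = 2L)
  lapply(firsts, function(q) c(q, q + 1L))
}

#' Attempt exchange moves across a population of chains
#'
#' For each neighbouring pair selected by [select_exchange_pairs()] at this
#' iteration, swaps the entire chain states (parameters, state path, stored
#' log-likelihood and log-prior) with probability
#' `min(1, exp(exchange_log_ratio(...)))`. Swapping whole states means no
#' particle filter needs to be re-run after an accepted exchange.
#'
#' @param population list of chain states (lists with `theta`, `log_lik`,
#'   `log_prior` and optionally `path`).
#' @param temperatures temperature of each chain.
#' @param iteration 1-based iteration counter (drives the rotating schedule).
#' @param u optional vector of uniforms, one per attempted pair (for replay);
#'   drawn from the ambient RNG when `NULL`.
#' @return List with the updated `population` and a data frame `log`
#'   (`iteration`, `q`, `r`, `log_ratio`, `accepted`).
#' @export
exchange_step <- function(population, temperatures, iteration, u = NULL) {
  pairs <- select_exchange_pairs(iteration, length(population))
  n <- length(pairs)
  if (is.null(u)) u <- stats::runif(n) else stopifnot(length(u) == n)
  log <- data.frame(iteration = rep(as.integer(iteration), n),
                    q = integer(n), r = integer(n),
                    log_ratio = numeric(n), accepted = logical(n))
  for (i in seq_len(n)) {
    q <- pairs[[i]][1L]; r <- pairs[[i]][2L]
    lr <- exchange_log_ratio(population[[q]]$log_lik, population[[r]]$log_lik,
                             temperatures[q], temperatures[r])
    acc <- log(u[i]) < min(0, lr)
    if (acc) {
      tmp <- population[[q]]
      population[[q]] <- population[[r]]
      population[[r]] <- tmp
    }
    log$q[i] <- q; log$r[i] <- r
    log$log_ratio[i] <- lr; log$accepted[i] <- acc
  }
  list(population = population, log = log)
}
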