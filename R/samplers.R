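# The shared sampling engine behind pmcmc() and ppmcmc().
#
# One iteration updates every chain (propose -> particle filter -> tempered
# pseudo-marginal accept/reject) and then attempts rotating neighbouring-pair
# exchange moves. pmcmc() is the single-chain, temperature-1 case of the same
# engine, so a one-chain ppmcmc() run replays a pmcmc() run exactly under the
# same seed.

run_population_engine <- function(model, prior, n_iter, temperatures,
                                  particles, proposal_diags, theta_init,
                                  burn_in, seed, resample, save_paths,
                                  sampler) {
  M <- length(temperatures)
  lp <- as_log_prior(prior)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("'n_iter' must be at least 1")
  if (burn_in < 0L || burn_in >= n_iter)
    stop("'burn_in' must be nonnegative and smaller than 'n_iter'")
  if (length(proposal_diags) != M)
    stop("need one proposal covariance diagonal per chain")

  stream_names <- c("init", paste0("mcmc_", seq_len(M)),
                    paste0("pf_", seq_len(M)), "exchange")
  streams <- rng_streams(seed, stream_names)
  stream_seeds <- lapply(streams, function(e) e$state)

  # initial parameter values: prior draws unless supplied
  if (is.null(theta_init)) {
    if (is.null(lp$sample))
      stop("'theta_init' must be supplied when the prior has no sampler")
    theta_init <- with_stream(streams$init,
                              t(vapply(seq_len(M), function(j) lp$sample(),
                                       numeric(lp$n_theta))))
    if (lp$n_theta == 1L) theta_init <- matrix(theta_init, ncol = 1L)
  } else {
    if (is.vector(theta_init) && !is.list(theta_init))
      theta_init <- matrix(theta_init, nrow = M, ncol = length(theta_init),
                           byrow = TRUE)
    theta_init <- as.matrix(theta_init)
    if (nrow(theta_init) != M)
      stop("'theta_init' must supply one parameter vector per chain")
  }
  d <- ncol(theta_init)
  for (j in seq_len(M)) {
    if (length(proposal_diags[[j]]) != d)
      stop("proposal covariance diagonals must match the parameter dimension")
    if (any(proposal_diags[[j]] <= 0))
      stop("proposal covariance diagonals must be positive")
  }

  # iteration 1: run the particle filter at theta_init, no accept/reject
  pop <- vector("list", M)
  n_pf <- integer(M); n_prior_reject <- integer(M); n_accept <- integer(M)
  for (j in seq_len(M)) {
    lp0 <- lp$log_density(theta_init[j, ])
    if (!is.finite(lp0))
      stop("initial parameter value for chain ", j,
           " lies outside the prior support")
    pf <- with_stream(streams[[paste0("pf_", j)]],
                      particle_filter(model, theta_init[j, ], particles,
                                      resample, save_history = save_paths))
    n_pf[j] <- n_pf[j] + 1L
    pop[[j]] <- chain_state(theta_init[j, ], pf$log_likelihood, lp0, pf$path)
  }

  theta_names <- colnames(theta_init)
  if (is.null(theta_names)) theta_names <- model$theta_names
  if (is.null(theta_names)) theta_names <- paste0("theta", seq_len(d))

  samples <- matrix(NA_real_, n_iter, d, dimnames = list(NULL, theta_names))
  log_lik <- numeric(n_iter); log_prior <- numeric(n_iter)
  accepted <- rep(NA, n_iter)
  samples[1L, ] <- pop[[1L]]$theta
  log_lik[1L] <- pop[[1L]]$log_lik
  log_prior[1L] <- pop[[1L]]$log_prior

  max_ex <- if (M > 1L) (n_iter - 1L) * ((M + 1L) %/% 2L) else 0L
  ex_it <- integer(max_ex); ex_q <- integer(max_ex); ex_r <- integer(max_ex)
  ex_lr <- numeric(max_ex); ex_acc <- logical(max_ex)
  n_ex <- 0L

  for (i in seq_len(n_iter)[-1L]) {
    for (j in seq_len(M)) {
      sj <- streams[[paste0("mcmc_", j)]]
      mv <- with_stream(sj, list(theta = propose_theta(pop[[j]]$theta,
                                                       proposal_diags[[j]]),
                                 u = stats::runif(1L)))
      lp_star <- lp$log_density(mv$theta)
      if (!is.finite(lp_star)) {
        n_prior_reject[j] <- n_prior_reject[j] + 1L
        acc <- FALSE
      } else {
        pf <- with_stream(streams[[paste0("pf_", j)]],
                          particle_filter(model, mv$theta, particles,
                                          resample, save_history = save_paths))
        n_pf[j] <- n_pf[j] + 1L
        cand <- chain_state(mv$theta, pf$log_likelihood, lp_star, pf$path)
        ratio <- tempered_log_acceptance(pop[[j]], cand, temperatures[j])
        acc <- log(mv$u) < min(0, ratio)
        if (acc) {
          pop[[j]] <- cand
          n_accept[j] <- n_accept[j] + 1L
        }
      }
      if (j == 1L) accepted[i] <- acc
    }

    if (M > 1L) {
      ex <- with_stream(streams$exchange,
                        exchange_step(pop, temperatures, i))
      pop <- ex$population
      k <- nrow(ex$log)
      if (k > 0L) {
        idx <- n_ex + seq_len(k)
        ex_it[idx] <- ex$log$iteration; ex_q[idx] <- ex$log$q
        ex_r[idx] <- ex$log$r; ex_lr[idx] <- ex$log$log_ratio
        ex_acc[idx] <- ex$log$accepted
        n_ex <- n_ex + k
      }
    }

    samples[i, ] <- pop[[1L]]$theta
    log_lik[i] <- pop[[1L]]$log_lik
    log_prior[i] <- pop[[1L]]$log_prior
  }

  exchange_log <- data.frame(iteration = ex_it[seq_len(n_ex)],
                             q = ex_q[seq_len(n_ex)], r = ex_r[seq_len(n_ex)],
                             log_ratio = ex_lr[seq_len(n_ex)],
                             accepted = ex_acc[seq_len(n_ex)])

  structure(
    list(samples = samples, log_lik = log_lik, log_prior = log_prior,
         accepted = accepted, burn_in = as.integer(burn_in),
         n_iter = n_iter, n_chains = M, temperatures = temperatures,
         particles = as.integer(particles), proposal = proposal_diags,
         theta_init = theta_init, resample = resample, seed = seed,
         n_pf = n_pf, n_prior_reject = n_prior_reject, n_accept = n_accept,
         exchange = exchange_log, state_path = pop[[1L]]$path,
         model_name = model$name, n_steps = model$n_steps,
         stream_seeds = stream_seeds, sampler = sampler),
    class = if (M > 1L || sampler == "ppmcmc") c("ppmcmc", "pmcmc") else "pmcmc")
}

#' Particle MCMC for state-space models
#'
#' Single-chain pseudo-marginal Metropolis-Hastings: each iteration proposes
#' a parameter vector by a Gaussian random walk, runs a bootstrap particle
#' filter to obtain an unbiased likelihood estimate and a candidate state
#' path, and accepts the joint candidate with the pseudo-marginal ratio.
#' On rejection the previous sample, path and stored log-likelihood are
#' replicated; stored estimates are never recomputed. The first iteration
#' initialises the chain (particle filter only, no accept/reject).
#'
#' @param model an [ssm_model()] bound to its data, e.g. from
#'   [methylation_ssm()] or [linear_gaussian_ssm()].
#' @param prior a [gamma_prior()] or a log-density `function(theta)`.
#' @param n_iter total number of iterations (including burn-in).
#' @param burn_in number of initial iterations flagged for exclusion from
#'   diagnostics (default 1000 of 11000).
#' @param particles number of particles per filter run.
#' @param proposal diagonal of the Gaussian random-walk covariance
#'   (variances, one per parameter component).
#' @param theta_init initial parameter vector; drawn from the prior when
#'   `NULL` (requires a `gamma_prior`).
#' @param seed master seed; spawns independent substreams for proposals,
#'   particle filtering and initialisation. Drawn from the ambient RNG when
#'   `NULL` and recorded in the result.
#' @param resample `"rsr"` (default) or `"multinomial"`.
#' @param save_paths keep the sampled state path of the current sample
#'   (memory grows with `T`).
#' @return An object of class `"pmcmc"`; see [summary.pmcmc()],
#'   [as.matrix.pmcmc()], [plot.pmcmc()].
#' @examples
#' d <- simulate_methylation(30, tissue = "single", seed = 1)
#' fit <- pmcmc(methylation_ssm(d), methylation_prior("single"),
#'              n_iter = 50, burn_in = 10, particles = 64,
#'              proposal = c(0.15, 0.008), theta_init = c(0.2, 0.02), seed = 1)
#' summary(fit)
#' @references Andrieu, C., Doucet, A., Holenstein, R. (2010). Particle
#'   Markov chain Monte Carlo methods. JRSS-B 72(3).
#' @export
pmcmc <- function(model, prior, n_iter = 11000, burn_in = 1000,
                  particles = 1024, proposal, theta_init = NULL, seed = NULL,
                  resample = c("rsr", "multinomial"), save_paths = FALSE) {
  resample <- match.arg(resample)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  run_population_engine(model, prior, n_iter, temperatures = 1,
                        particles = particles,
                        proposal_diags = list(as.numeric(proposal)),
                        theta_init = theta_init, burn_in = burn_in,
                        seed = seed, resample = resample,
                        save_paths = save_paths, sampler = "pmcmc")
}

#' Population-based particle MCMC
#'
#' Runs `n_chains` particle-MCMC chains on a strictly increasing temperature
#' ladder starting at 1. Chain `j` accepts with the tempered pseudo-marginal
#' ratio (likelihood estimates raised to `1/Temp_j`); after every chain has
#' been updated, rotating neighbouring-pair exchange moves swap entire chain
#' states with probability `min(1, exp(exchange_log_ratio(...)))`, using only
#' stored likelihood estimates. Hot chains explore a smoothed posterior and
#' feed the cold chain through exchanges, letting it escape local modes; only
#' chain 1 (temperature 1, exact posterior) is retained.
#'
#' With `n_chains = 1` the algorithm, RNG stream layout and output coincide
#' exactly with [pmcmc()].
#'
#' @inheritParams pmcmc
#' @param n_chains number of chains `M >= 1`.
#' @param temperatures explicit ladder (first entry must be 1, strictly
#'   increasing); built additively via
#'   `build_temperature_ladder(n_chains, increment)` when `NULL`.
#' @param increment additive temperature step used when `temperatures` is
#'   `NULL` (default 2.5).
#' @param proposal per-chain proposal covariance diagonals: a list of length
#'   `n_chains`, or a single numeric vector used for every chain. See
#'   [methylation_chain_proposals()] for the methylation defaults.
#' @param theta_init matrix with one initial parameter vector per chain (or a
#'   single vector used for all chains); independent prior draws when `NULL`.
#' @return An object of class `c("ppmcmc", "pmcmc")` carrying chain 1's trace
#'   plus the exchange log (`$exchange`).
#' @examples
#' d <- simulate_methylation(30, tissue = "multi", seed = 1)
#' fit <- ppmcmc(methylation_ssm(d), methylation_prior("multi"),
#'               n_iter = 50, burn_in = 10, n_chains = 2, particles = 64,
#'               proposal = methylation_chain_proposals(2),
#'               theta_init = c(0.2, 10, 0.02), seed = 1)
#' summary(fit)
#' @export
ppmcmc <- function(model, prior, n_iter = 11000, burn_in = 1000,
                   n_chains = 2, particles = 1024, temperatures = NULL,
                   increment = 2.5, proposal, theta_init = NULL, seed = NULL,
                   resample = c("rsr", "multinomial"), save_paths = FALSE) {
  resample <- match.arg(resample)
  n_chains <- as.integer(n_chains)
  if (is.null(temperatures)) {
    temperatures <- build_temperature_ladder(n_chains, increment)
  } else {
    if (length(temperatures) != n_chains)
      stop("'temperatures' must have one entry per chain")
    if (temperatures[1L] != 1)
      stop("the first temperature must be exactly 1")
    if (n_chains > 1L && any(diff(temperatures) <= 0))
      stop("'temperatures' must be strictly increasing")
  }
  if (!is.list(proposal)) proposal <- rep(list(as.numeric(proposal)), n_chains)
  if (length(proposal) != n_chains)
    stop("'proposal' must supply one covariance diagonal per chain")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  run_population_engine(model, prior, n_iter, temperatures = temperatures,
                        particles = particles, proposal_diags = proposal,
                        theta_init = theta_init, burn_in = burn_in,
                        seed = seed, resample = resample,
                        save_paths = save_paths, sampler = "ppmcmc")
}
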