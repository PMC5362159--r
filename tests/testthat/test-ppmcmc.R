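test_that("additive temperature ladders", {
  expect_equal(build_temperature_ladder(1), 1)
  expect_equal(build_temperature_ladder(5, 2.5), c(1, 3.5, 6, 8.5, 11))
  expect_equal(build_temperature_ladder(2, 2.5), c(1, 3.5))
  expect_error(build_temperature_ladder(0), "at least 1")
  expect_error(build_temperature_ladder(3, t1 = 2), "exactly 1")
  expect_error(build_temperature_ladder(3, increment = 0), "positive")
})

test_that("tempered ratio at temperature 1 equals the plain ratio bit-for-bit", {
  set.seed(71)
  for (i in 1:1000) {
    cur <- list(log_lik = rnorm(1, sd = 50), log_prior = rnorm(1, sd = 5))
    prop <- list(log_lik = rnorm(1, sd = 50), log_prior = rnorm(1, sd = 5))
    expect_identical(tempered_log_acceptance(cur, prop, temp = 1),
                     log_acceptance_ratio(cur, prop))
  }
})

test_that("tempering scales only the likelihood term", {
  st <- function(ll, lp) list(log_lik = ll, log_prior = lp)
  # equal likelihood estimates, prior ratio e: log ratio 1 at any temperature
  expect_equal(tempered_log_acceptance(st(-20, -3), st(-20, -2), 3.5), 1)
  # infinite-temperature limit: prior-only ratio
  expect_equal(tempered_log_acceptance(st(-20, -3), st(-800, -2), 1e12), 1,
               tolerance = 1e-9)
  expect_identical(tempered_log_acceptance(st(-20, -3), st(-Inf, -2), 3.5), -Inf)
  expect_error(tempered_log_acceptance(st(0, 0), st(0, 0), 0.5), "at least 1")
})

test_that("exchange ratio matches the closed form", {
  expect_equal(exchange_log_ratio(-5, -5, 1, 3.5), 0)    # identical estimates
  expect_equal(exchange_log_ratio(-2, -9, 2, 2), 0)      # equal temperatures
  r <- exchange_log_ratio(0, log(10), 1, 3.5)
  expect_equal(r, log(10) * (1 - 1 / 3.5))
  expect_equal(r, 1.6447, tolerance = 1e-4)
  expect_identical(exchange_log_ratio(-Inf, -5, 1, 3.5), -Inf)
})

test_that("exchange pairs rotate between odd and even alignments", {
  expect_identical(select_exchange_pairs(1, 1), list())
  expect_identical(select_exchange_pairs(2, 1), list())
  expect_equal(select_exchange_pairs(3, 5), list(c(1L, 2L), c(3L, 4L)))
  expect_equal(select_exchange_pairs(4, 5), list(c(2L, 3L), c(4L, 5L)))
  expect_equal(select_exchange_pairs(1, 2), list(c(1L, 2L)))
  expect_identical(select_exchange_pairs(2, 2), list())
  # pairs within one iteration are disjoint
  for (M in 2:7) {
    for (it in 1:2) {
      idx <- unlist(select_exchange_pairs(it, M))
      expect_identical(anyDuplicated(idx), 0L)
    }
  }
})

test_that("exchange step swaps whole states and is an involution", {
  pop <- list(
    list(theta = c(0.2, 0.02), log_lik = -100, log_prior = -1, path = 1:3),
    list(theta = c(10, 0.05), log_lik = -90, log_prior = -2, path = 4:6))

  # degenerate equal-temperature ladder: every attempted swap is accepted
  res <- exchange_step(pop, temperatures = c(1, 1), iteration = 1, u = 0.999)
  expect_true(res$log$accepted)
  expect_equal(res$population[[1]]$theta, c(10, 0.05))
  expect_equal(res$population[[1]]$path, 4:6)
  expect_equal(res$population[[2]]$log_lik, -100)

  # applying the accepted swap twice restores the population
  res2 <- exchange_step(res$population, c(1, 1), iteration = 1, u = 0.5)
  expect_identical(res2$population, pop)

  # replay with fixed uniforms against the hand-computed ratio
  lr <- (pop[[2]]$log_lik - pop[[1]]$log_lik) * (1 / 1 - 1 / 3.5)  # > 0 here
  res3 <- exchange_step(pop, c(1, 3.5), iteration = 1,
                        u = exp(min(0, lr)) * 0.99)  # just below the bar
  expect_true(res3$log$accepted)
  expect_equal(res3$log$log_ratio, lr)
  lr_neg <- (pop[[1]]$log_lik - pop[[2]]$log_lik) * (1 / 1 - 1 / 3.5)
  res4 <- exchange_step(list(pop[[2]], pop[[1]]), c(1, 3.5), iteration = 1,
                        u = exp(lr_neg) * 1.01)  # just above the bar
  expect_false(res4$log$accepted)

  # even iteration with two chains: nothing to attempt
  res5 <- exchange_step(pop, c(1, 3.5), iteration = 2)
  expect_identical(res5$population, pop)
  expect_equal(nrow(res5$log), 0L)
})

test_that("a one-chain population run replays the single-chain sampler", {
  d <- simulate_methylation(15, tissue = "single", seed = 3)
  m <- methylation_ssm(d)
  pr <- methylation_prior("single")
  f1 <- pmcmc(m, pr, n_iter = 60, burn_in = 10, particles = 32,
              proposal = c(0.15, 0.008), theta_init = c(0.2, 0.02), seed = 42)
  f2 <- ppmcmc(m, pr, n_iter = 60, burn_in = 10, n_chains = 1, particles = 32,
               proposal = list(c(0.15, 0.008)), theta_init = c(0.2, 0.02),
               seed = 42)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$log_lik, f2$log_lik)
  expect_identical(f1$accepted, f2$accepted)
  expect_equal(nrow(f2$exchange), 0L)
})

test_that("chains use distinct independent filter RNG substreams", {
  d <- simulate_methylation(15, tissue = "multi", seed = 3)
  fit <- ppmcmc(methylation_ssm(d), methylation_prior("multi"),
                n_iter = 30, burn_in = 5, n_chains = 3, particles = 32,
                proposal = methylation_chain_proposals(3),
                theta_init = c(0.2, 10, 0.02), seed = 13)
  seeds <- fit$stream_seeds[c("pf_1", "pf_2", "pf_3")]
  # the two likelihood estimates entering an exchange ratio come from
  # distinct substreams: all initial stream states must differ
  for (a in 1:2) for (b in (a + 1):3) {
    expect_false(identical(seeds[[a]], seeds[[b]]))
  }
})

test_that("exchange acceptance drops as the temperature gap widens", {
  d <- simulate_methylation(30, tissue = "multi", seed = 8)
  m <- methylation_ssm(d)
  pr <- methylation_prior("multi")
  rates <- vapply(c(2.5, 60), function(inc) {
    fit <- ppmcmc(m, pr, n_iter = 500, burn_in = 100, n_chains = 2,
                  particles = 64, increment = inc,
                  proposal = methylation_chain_proposals(2),
                  theta_init = c(0.2, 10, 0.02), seed = 14)
    mean(fit$exchange$accepted)
  }, numeric(1))
  expect_gt(rates[1], rates[2])
})

test_that("population sampler recovers an exact-likelihood bimodal target", {
  # reduced-size companion of the acceptance-scale occupancy study
  m <- exact_likelihood_model(bimodal_log_density)
  fit <- ppmcmc(m, prior = flat_log_prior, n_iter = 20000, burn_in = 2000,
                n_chains = 4, particles = 2,
                proposal = list(1, 4, 9, 16),
                theta_init = matrix(c(0, 10, 0, 10), ncol = 1), seed = 15)
  s <- as.matrix(fit)[, 1]
  occ0 <- mean(s < 5)
  expect_gt(occ0, 0.5 - 0.1)
  expect_lt(occ0, 0.5 + 0.1)
})
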