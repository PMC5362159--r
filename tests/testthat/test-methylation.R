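test_that("positions start at 1 with uniform gaps in [1, 100]", {
  set.seed(81)
  expect_identical(methylation_positions(1), 1L)
  pos <- methylation_positions(1e4)
  gaps <- diff(pos)
  expect_identical(pos[1], 1L)
  expect_true(all(gaps >= 1 & gaps <= 100))
  expect_true(all(gaps == round(gaps)))
  # discrete-uniform mean 50.5
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 50.5), 3 * se)
  # strictly increasing for any seed
  for (s in 1:5) {
    set.seed(s)
    expect_true(all(diff(methylation_positions(500)) >= 1))
  }
})

test_that("single-tissue transition variance scales linearly with the gap", {
  expect_identical(transition_single(1.7, 0, gap = 5), 1.7)  # zero variance
  set.seed(82)
  n <- 1e5
  dr5 <- transition_single(rep(0, n), 0.2, gap = 5)
  v <- var(dr5)
  expect_lt(abs(v - 1.0), 3 * v * sqrt(2 / (n - 1)))
  dr1 <- transition_single(rep(0, n), 0.2, gap = 1)
  dr10 <- transition_single(rep(0, n), 0.2, gap = 10)
  expect_equal(var(dr10) / var(dr1), 10, tolerance = 0.15)
})

test_that("mixture transition has the two-component law", {
  set.seed(83)
  n <- 1e5
  # collapse: equal variances reduce to the single-tissue law
  a <- transition_mixture(rep(0, n), 0.3, 0.3, gap = 2)
  b <- transition_single(rep(0, n), 0.3, gap = 2)
  expect_gt(ks.test(a, b)$p.value, 0.01)
  # mixture variance 0.5*0.2 + 0.5*10 = 5.1 at unit gap
  dr <- transition_mixture(rep(0, n), 0.2, 10.0, gap = 1)
  v <- var(dr)
  se_v <- sqrt((mean(dr^4) - v^2) / n)  # heavy-tailed: moment-based SE
  expect_lt(abs(v - 5.1), 3 * se_v)
  # equal component weights: small-variance draws occur half the time
  frac1 <- mean(abs(dr) < qnorm(0.999, 0, sqrt(0.2)))
  expected <- 0.5 * 0.998 + 0.5 * (pnorm(qnorm(0.999, 0, sqrt(0.2)), 0, sqrt(10)) -
                                     pnorm(-qnorm(0.999, 0, sqrt(0.2)), 0, sqrt(10)))
  expect_lt(abs(frac1 - expected), 3 * sqrt(0.25 / n) + 0.01)
})

test_that("replicate log-weight reduces to the binomial pmf when beta = 0", {
  # empty binomial: no trials, weight 1
  expect_identical(replicate_log_weight(c(0, 1), y = c(0, 0, 0, 0),
                                        n = c(0, 0, 0, 0), beta_sq = 0),
                   c(0, 0))
  # one replicate, y = 1 of n = 2 at p = 0.5: log(0.5)
  lw <- replicate_log_weight(0, y = 1, n = 2, beta_sq = 0)
  expect_equal(lw, log(0.5))
  expect_error(replicate_log_weight(0, y = 3, n = 2, beta_sq = 0))
})

test_that("mean weight matches quadrature over the random effect", {
  # E[exp(weight)] = integral Binom(y; n, plogis(z)) N(z; x, beta) dz
  x <- 0.4; y <- 7; n <- 20; beta_sq <- 0.3
  marginal <- integrate(function(z)
    dbinom(y, n, plogis(z)) * dnorm(z, x, sqrt(beta_sq)),
    lower = x - 10, upper = x + 10, rel.tol = 1e-10)$value
  set.seed(84)
  w <- exp(replicate_log_weight(rep(x, 1e5), y = y, n = n, beta_sq = beta_sq))
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - marginal), 3 * se)
})

test_that("simulated datasets follow the stated generation recipe", {
  d1 <- simulate_methylation(200, tissue = "single", seed = 4)
  expect_equal(d1$theta_true, c(sigma1_sq = 0.2, beta_sq = 0.02))
  d2 <- simulate_methylation(200, tissue = "multi", seed = 4)
  expect_equal(d2$theta_true, c(sigma1_sq = 0.2, sigma2_sq = 10.0, beta_sq = 0.02))
  for (d in list(d1, d2)) {
    expect_true(all(d$y >= 0 & d$y <= d$n))
    expect_true(all(d$n >= 1 & d$n <= 50))
    expect_true(all(diff(d$delta) >= 1 & diff(d$delta) <= 100))
    expect_equal(dim(d$y), c(200, 4))
  }
  # determinism under a fixed seed; ambient RNG untouched
  set.seed(999); before <- runif(1)
  d3 <- simulate_methylation(200, tissue = "multi", seed = 4)
  expect_identical(d3$y, d2$y)
  expect_identical(d3$x_true, d2$x_true)
  set.seed(999)
  expect_identical(runif(1), before)
  expect_error(simulate_methylation(0), "at least 1")
  expect_error(simulate_methylation(10, theta = c(0.2, 0.02), tissue = "multi"),
               "3 components")
})

test_that("the mixture walk is symmetric under swapping its variances", {
  # label-switching symmetry: increments with (0.2, 10) and (10, 0.2) are
  # indistinguishable; this symmetry is what makes the posterior bimodal
  set.seed(85)
  n <- 2e4
  inc_a <- transition_mixture(rep(0, n), 0.2, 10.0, gap = 3)
  inc_b <- transition_mixture(rep(0, n), 10.0, 0.2, gap = 3)
  expect_gt(ks.test(inc_a, inc_b)$p.value, 0.01)
})

test_that("filter estimate is unbiased for the random-effect-integrated likelihood", {
  # T = 3 toy with one informative replicate; brute-force reference via
  # nested quadrature over the states (the random effect is integrated
  # inside the per-step observation marginal)
  d <- simulate_methylation(3, tissue = "single", seed = 21)
  d$y[, 2:4] <- 0L; d$n[, 2:4] <- 0L  # keep one replicate informative
  theta <- c(0.3, 0.1)

  marg_obs <- function(x, t) {
    vapply(x, function(xi)
      integrate(function(z) dbinom(d$y[t, 1], d$n[t, 1], plogis(z)) *
                  dnorm(z, xi, sqrt(theta[2])),
                lower = xi - 12, upper = xi + 12, rel.tol = 1e-9)$value,
      numeric(1))
  }
  grid <- seq(-12, 12, length.out = 401)
  dx <- diff(grid[1:2])
  gaps <- diff(d$delta)
  # discretised forward recursion over the state grid
  alpha <- dnorm(grid, 0, 1) * marg_obs(grid, 1)
  for (t in 2:3) {
    trans <- outer(grid, grid, function(xp, xc)
      dnorm(xc, xp, sqrt(theta[1] * gaps[t - 1])))
    alpha <- as.vector(alpha %*% trans) * dx * marg_obs(grid, t)
  }
  exact <- sum(alpha) * dx

  m <- methylation_ssm(d)
  set.seed(86)
  lik <- replicate(3000, exp(particle_filter(m, theta, particles = 64,
                                             save_history = FALSE)$log_likelihood))
  se <- sd(lik) / sqrt(length(lik))
  expect_lt(abs(mean(lik) - exact), 3 * se)
})

test_that("compiled and generic filter paths agree in distribution", {
  d <- simulate_methylation(25, tissue = "multi", seed = 31)
  m <- methylation_ssm(d)
  theta <- c(0.2, 10, 0.02)
  set.seed(87)
  ll_cpp <- replicate(300, particle_filter(m, theta, 128,
                                           save_history = FALSE)$log_likelihood)
  ll_r <- replicate(300, particle_filter(m, theta, 128,
                                         save_history = TRUE)$log_likelihood)
  pooled_se <- sqrt(var(exp(ll_cpp - max(ll_cpp, ll_r))) / 300 +
                      var(exp(ll_r - max(ll_cpp, ll_r))) / 300)
  expect_lt(abs(mean(exp(ll_cpp - max(ll_cpp, ll_r))) -
                  mean(exp(ll_r - max(ll_cpp, ll_r)))), 3 * pooled_se)
})
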