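# poppmcmc

Pseudo-marginal inference for state-space models (SSMs) with unknown
parameters, aimed at problems where the likelihood of the parameters has no
closed form but can be estimated without bias by a particle filter. The
package is written for statisticians and computational biologists who need
full Bayesian inference on hidden-state sequence models — the bundled case
study is DNA-methylation profiling from bisulfite-test counts — and in
particular for posteriors that are **multi-modal**, where a single MCMC
chain mixes hopelessly.

## What it implements

For an SSM
`X1 ~ e(X1)`, `Xt ~ f(Xt | Xt-1, θ)`, `yt ~ g(yt | Xt, θ)`
with prior `ρ(θ)`, the target is the joint posterior
`p(X_{1:T}, θ | y_{1:T})`.

* **Bootstrap particle filter** (`particle_filter()`): log-domain weights
  with max-log-weight renormalisation, Residual Systematic Resampling (one
  uniform per step, counts `r_m = ⌊(w_m − u)P⌋ + 1`), unbiased likelihood
  estimate `log l̃ = Σ_t log((1/P) Σ_p W_t^p)` and an ancestry-traced
  state path.
* **Particle MCMC** (`pmcmc()`): Gaussian random-walk proposals and the
  pseudo-marginal acceptance ratio
  `a = [ρ(θ*) l̃(y|θ*)] / [ρ(θ) l̃(y|θ)]`; converges to the exact
  posterior for any particle count.
* **Population-based particle MCMC** (`ppmcmc()`): `M` chains on a
  temperature ladder `1 = T1 < … < TM` (additive increment 2.5 by
  default); chain `j` accepts with the likelihood estimates raised to
  `1/Tj`, and rotating neighbouring-pair exchange moves swap whole chain
  states with log-ratio `(log l̃_r − log l̃_q)(1/T_q − 1/T_r)`, needing no
  extra filter runs. Hot chains cross between modes and feed the cold
  chain, whose samples are the output.
* **Methylation SSMs + synthetic data** (`methylation_ssm()`,
  `simulate_methylation()`): logit-probability random walk with
  gap-scaled variance (single tissue) or an equal-weight two-component
  mixture walk (multi tissue, giving a label-switching bimodal posterior),
  binomial observations over four replicates with logit-normal random
  effects handled by a random-weight filter.
* **Diagnostics** (`effective_sample_size()`, `kde_density()`, `kld()`,
  `reference_posterior_grid()`, `mode_occupancy()`): truncated-
  autocorrelation ESS, Gaussian KDE (bandwidth 0.85 in the case studies),
  Kullback–Leibler divergence on a grid, slice reference posteriors and
  KDE mode-occupancy analysis.

A thin command-line wrapper with `simulate` / `run-pmcmc` / `run-ppmcmc` /
`diagnose` subcommands ships in `inst/cli/ppmcmc-tool.R`.

## A worked example

```r
library(poppmcmc)

d <- simulate_methylation(200, tissue = "single", seed = 3)
fit <- pmcmc(methylation_ssm(d), methylation_prior("single"),
             n_iter = 4000, burn_in = 1000, particles = 600,
             proposal = methylation_proposal("single"),
             theta_init = d$theta_true, seed = 7)
summary(fit)
```

```
Posterior summary (methylation-single): 3000 retained samples after burn-in 1000
            mean     sd   2.5%    50%  97.5%      ess
sigma1_sq 0.1778 0.0761 0.0822 0.1503 0.3935 126.1024
beta_sq   0.0432 0.0401 0.0008 0.0282 0.1340  59.6847
chain-1 acceptance rate: 0.074
```

The walk-variance marginal concentrates near the generating value
`sigma1_sq = 0.2` (posterior mean 0.178) and the between-replicate
variance near its generating 0.02; the acceptance rate shows a moving
pseudo-marginal chain. `mode_occupancy()` on the retained `sigma1_sq`
samples reports a single mode, as expected for one tissue:

```r
mode_occupancy(as.matrix(fit)[, "sigma1_sq"], bandwidth = 0.85)
#    location occupancy
# 1 0.1771789         1
```

On multi-tissue data the two walk variances are exchangeable and the
posterior is bimodal; there `ppmcmc()` with as few as two chains visits
both modes while a single chain stays trapped in one — see the methods
vignette (`vignettes/population-particle-mcmc.Rmd`) for the model details,
tuning constants and the limits of the scaled-down studies.

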