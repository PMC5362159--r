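# S3 methods for fitted sampler objects.

#' Retained posterior samples as a matrix
#'
#' Drops the burn-in rows; one column per parameter component.
#'
#' @param x a fit from [pmcmc()] or [ppmcmc()].
#' @param ... unused.
#' @export
as.matrix.pmcmc <- function(x, ...) {
  keep <- seq.int(x$burn_in + 1L, x$n_iter)
  x$samples[keep, , drop = FALSE]
}

#' Posterior means of the retained samples
#'
#' @param object a fit from [pmcmc()] or [ppmcmc()].
#' @param ... unused.
#' @export
coef.pmcmc <- function(object, ...) {
  colMeans(as.matrix(object))
}

acceptance_rate <- function(x) {
  a <- x$accepted[-1L]  # iteration 1 is initialisation, no accept/reject
  mean(a, na.rm = TRUE)
}

#' @export
print.pmcmc <- function(x, ...) {
  cat(sprintf("%s fit (%s)\n",
              if (inherits(x, "ppmcmc")) "Population-based particle MCMC"
              else "Particle MCMC",
              x$model_name))
  cat(sprintf("  iterations: %d (burn-in %d)   particles: %d   chains: %d\n",
              x$n_iter, x$burn_in, x$particles, x$n_chains))
  if (x$n_chains > 1L)
    cat("  temperatures:", paste(format(x$temperatures), collapse = ", "), "\n")
  cat(sprintf("  chain-1 acceptance rate: %.3f\n", acceptance_rate(x)))
  cat("  posterior means:",
      paste(sprintf("%s = %.4g", colnames(x$samples), coef(x)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a particle MCMC fit
#'
#' Posterior means, standard deviations and quantiles of the retained
#' samples, chain-1 acceptance rate, effective sample sizes per component
#' and (for population runs) per-pair exchange acceptance rates.
#'
#' @param object a fit from [pmcmc()] or [ppmcmc()].
#' @param ... unused.
#' @export
summary.pmcmc <- function(object, ...) {
  s <- as.matrix(object)
  qs <- t(apply(s, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  ess <- vapply(seq_len(ncol(s)), function(k) {
    if (stats::var(s[, k]) == 0) NA_real_
    else effective_sample_size(s[, k])$ess
  }, numeric(1))
  tab <- cbind(mean = colMeans(s), sd = apply(s, 2L, stats::sd), qs, ess = ess)
  ex <- NULL
  if (nrow(object$exchange) > 0L) {
    e <- object$exchange
    pair <- paste0("(", e$q, ",", e$r, ")")
    ex <- data.frame(pair = sort(unique(pair)))
    ex$attempts <- as.integer(table(pair)[ex$pair])
    ex$accept_rate <- vapply(ex$pair,
                             function(p) mean(e$accepted[pair == p]),
                             numeric(1))
  }
  structure(list(table = tab, acceptance_rate = acceptance_rate(object),
                 exchange = ex, n_retained = nrow(s),
                 burn_in = object$burn_in, n_chains = object$n_chains,
                 particles = object$particles, n_pf = object$n_pf,
                 model_name = object$model_name),
            class = "summary.pmcmc")
}

#' @export
print.summary.pmcmc <- function(x, ...) {
  cat(sprintf("Posterior summary (%s): %d retained samples after burn-in %d\n",
              x$model_name, x$n_retained, x$burn_in))
  print(round(x$table, 4))
  cat(sprintf("chain-1 acceptance rate: %.3f\n", x$acceptance_rate))
  if (!is.null(x$exchange)) {
    cat("exchange acceptance by pair:\n")
    print(x$exchange, row.names = FALSE)
  }
  invisible(x)
}

#' Trace and marginal density plots
#'
#' One row per parameter component: the retained trace on the left and its
#' Gaussian kernel density estimate on the right.
#'
#' @param x a fit from [pmcmc()] or [ppmcmc()].
#' @param bandwidth KDE bandwidth (default 0.85).
#' @param ... passed to [plot()].
#' @export
plot.pmcmc <- function(x, bandwidth = 0.85, ...) {
  s <- as.matrix(x)
  d <- ncol(s)
  old <- graphics::par(mfrow = c(d, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in seq_len(d)) {
    nm <- colnames(s)[k]
    graphics::plot(s[, k], type = "l", xlab = "iteration (post burn-in)",
                   ylab = nm, main = paste("trace:", nm), ...)
    kd <- kde_density(s[, k], bandwidth = bandwidth)
    graphics::plot(kd$grid, kd$density, type = "l", xlab = nm,
                   ylab = "density", main = paste("marginal:", nm), ...)
  }
  invisible(x)
}
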