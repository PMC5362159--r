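# Named independent RNG substreams built on L'Ecuyer-CMRG.
#
# One master seed spawns a family of streams (per-chain proposal/accept,
# per-chain particle filter, exchange decisions, initialisation) so that runs
# are reproducible and the stream layout is identical between pmcmc() and
# ppmcmc() with one chain.

#' Spawn named independent RNG streams from one seed
#'
#' Uses the L'Ecuyer-CMRG generator and [parallel::nextRNGStream()] to derive
#' statistically independent substreams. The caller's global RNG state is
#' saved and restored.
#'
#' @param seed single integer master seed.
#' @param names character vector of stream names.
#' @return A named list of stream objects (environments holding the stream
#'   state), to be used with [with_stream()].
#' @keywords internal
rng_streams <- function(seed, names) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(names) >= 1L)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed))
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", length(names))
  names(out) <- names
  for (i in seq_along(names)) {
    e <- new.env(parent = emptyenv())
    e$state <- s
    e$name <- names[i]
    e$n_uses <- 0L
    out[[i]] <- e
    s <- parallel::nextRNGStream(s)
  }
  out
}

#' Evaluate an expression under a given RNG stream
#'
#' Swaps the stream's state into `.Random.seed`, evaluates `expr`, stores the
#' advanced state back into the stream and restores the previous global state.
#'
#' @param stream a stream from [rng_streams()].
#' @param expr expression to evaluate.
#' @keywords internal
with_stream <- function(stream, expr) {
  old <- save_rng_state()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    stream$n_uses <- stream$n_uses + 1L
    restore_rng_state(old)
  })
  expr
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with a locally seeded RNG, leaving the global state untouched.
# seed = NULL evaluates expr under the ambient RNG.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
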