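# Plain-text readers and writers: methylation datasets as TSV, traces and
# exchange logs as CSV, run metadata as JSON. All numeric CSV output keeps
# full double precision so a run is byte-reproducible from its metadata.

#' Write a methylation dataset to TSV
#'
#' Data columns `t delta y1..yK n1..nK` (tab-separated, 1-based `t`).
#' Optionally writes the ground-truth states to a companion TSV
#' (`t delta x_true`) and the generating parameters and seed to a JSON
#' sidecar.
#'
#' @param data a `"methylation_data"` object.
#' @param file path of the dataset TSV.
#' @param truth_file optional path for the ground-truth TSV.
#' @param meta_file optional path for the JSON metadata.
#' @export
write_methylation <- function(data, file, truth_file = NULL,
                              meta_file = NULL) {
  stopifnot(inherits(data, "methylation_data"))
  K <- data$n_replicates
  df <- data.frame(t = seq_len(data$n_positions), delta = data$delta)
  ymat <- as.data.frame(data$y); names(ymat) <- paste0("y", seq_len(K))
  nmat <- as.data.frame(data$n); names(nmat) <- paste0("n", seq_len(K))
  utils::write.table(cbind(df, ymat, nmat), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth_file)) {
    truth <- data.frame(t = df$t, delta = df$delta,
                        x_true = format(data$x_true, digits = 17))
    utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(meta_file)) {
    jsonlite::write_json(
      list(tissue = data$tissue, n_positions = data$n_positions,
           n_replicates = K, theta_true = data$theta_true,
           seed = data$seed),
      meta_file, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(file)
}

#' Read a methylation dataset from TSV
#'
#' Column order is header-driven; the file must provide `t`, `delta`,
#' `y1..yK` and `n1..nK`. Validates integer counts, `y <= n` and strictly
#' increasing positions, reporting the offending row on failure.
#'
#' @param file dataset TSV path.
#' @param truth_file optional ground-truth TSV (adds `x_true`).
#' @return A `"methylation_data"` object (without generating parameters
#'   unless a truth/metadata source supplies them).
#' @export
read_methylation <- function(file, truth_file = NULL) {
  df <- utils::read.delim(file, check.names = FALSE)
  if (!all(c("t", "delta") %in% names(df)))
    stop("dataset file must contain columns 't' and 'delta'")
  ycols <- sort(grep("^y[0-9]+$", names(df), value = TRUE))
  ncols <- sort(grep("^n[0-9]+$", names(df), value = TRUE))
  if (length(ycols) == 0L || length(ycols) != length(ncols))
    stop("dataset file must contain matching y1..yK and n1..nK columns")
  ord <- order(df$t)
  df <- df[ord, , drop = FALSE]
  y <- as.matrix(df[, ycols, drop = FALSE])
  n <- as.matrix(df[, ncols, drop = FALSE])
  incomplete <- which(!stats::complete.cases(df[, c("t", "delta", ycols, ncols)]))
  if (length(incomplete) > 0L)
    stop(sprintf("row %d: incomplete or non-numeric record", incomplete[1L]))
  if (!is.numeric(y) || !is.numeric(n) ||
      any(y != round(y)) || any(n != round(n)))
    stop("success and trial counts must be integers")
  bad <- which(rowSums(y > n) > 0L)
  if (length(bad) > 0L)
    stop(sprintf("row %d: more successes than trials (y > n)", bad[1L]))
  if (any(y < 0) || any(n < 1))
    stop("counts must satisfy y >= 0 and n >= 1")
  dd <- diff(df$delta)
  if (length(dd) > 0L && any(dd < 1))
    stop(sprintf("row %d: positions must be strictly increasing",
                 which(dd < 1)[1L] + 1L))
  x_true <- NULL
  if (!is.null(truth_file)) {
    tr <- utils::read.delim(truth_file)
    x_true <- tr$x_true[order(tr$t)]
  }
  structure(list(n_positions = nrow(df), delta = as.integer(df$delta),
                 y = unname(y), n = unname(n), x_true = x_true,
                 theta_true = NULL, tissue = "single",
                 n_replicates = length(ycols), seed = NULL),
            class = "methylation_data")
}

#' Write a sampler trace to CSV
#'
#' One row per iteration: `iteration`, the parameter components, the stored
#' log-likelihood estimate and log-prior, and the chain-1 acceptance flag.
#'
#' @param fit a [pmcmc()] / [ppmcmc()] fit.
#' @param file output CSV path.
#' @export
write_trace <- function(fit, file) {
  s <- fit$samples
  df <- data.frame(iteration = seq_len(fit$n_iter))
  for (k in seq_len(ncol(s))) df[[colnames(s)[k]]] <- format(s[, k], digits = 17)
  df$log_lik <- format(fit$log_lik, digits = 17)
  df$log_prior <- format(fit$log_prior, digits = 17)
  df$accepted <- fit$accepted
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a sampler trace CSV written by [write_trace()]
#'
#' @param file trace CSV path.
#' @return List with `samples` (matrix), `log_lik`, `log_prior`, `accepted`.
#' @export
read_trace <- function(file) {
  df <- utils::read.csv(file)
  fixed <- c("iteration", "log_lik", "log_prior", "accepted")
  theta_cols <- setdiff(names(df), fixed)
  list(samples = as.matrix(df[, theta_cols, drop = FALSE]),
       log_lik = df$log_lik, log_prior = df$log_prior,
       accepted = as.logical(df$accepted))
}

#' Write the exchange log of a population run to CSV
#'
#' @param fit a [ppmcmc()] fit.
#' @param file output CSV path.
#' @export
write_exchanges <- function(fit, file) {
  utils::write.csv(fit$exchange, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write run metadata (full configuration echo) as JSON
#'
#' Records everything needed to replay the run: sampler type, seed,
#' iteration counts, particles, temperatures, proposal diagonals and model
#' identity.
#'
#' @param fit a [pmcmc()] / [ppmcmc()] fit.
#' @param file output JSON path.
#' @export
write_run_metadata <- function(fit, file) {
  jsonlite::write_json(
    list(sampler = fit$sampler, model = fit$model_name,
         n_iter = fit$n_iter, burn_in = fit$burn_in,
         n_chains = fit$n_chains, particles = fit$particles,
         temperatures = fit$temperatures, proposal = fit$proposal,
         theta_init = apply(fit$theta_init, 1L, as.numeric,
                            simplify = FALSE),
         resample = fit$resample, seed = fit$seed),
    file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
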