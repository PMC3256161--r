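#' Full pipeline configuration
#'
#' Bundles every tunable of the trace-to-machine pipeline.  Defaults follow
#' standard practice for single-molecule spectra: permille certainty
#' quantiles (`q = 0.001`), up to four mixture components, splitting test
#' at `alpha = 0.05`, pruning off.
#'
#' @param q tail quantile of the certainty partition.
#' @param k_max largest mixture size tried during AIC selection.
#' @param k_fixed optional fixed component count (bypasses selection).
#' @param alpha significance level of the state-splitting test.
#' @param max_length maximum history length; `NULL` = choose from the data
#'   via [suggest_max_length()].
#' @param test `"chi2"` or `"ks"`.
#' @param criterion mixture selection criterion, `"aic"` or `"bic"`.
#' @param prune_threshold transition-probability pruning cutoff (0 = off).
#' @param dt sampling interval in seconds.
#' @param seed integer seed controlling all randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(q = 0.001, k_max = 4L, k_fixed = NULL,
                            alpha = 0.05, max_length = NULL,
                            test = c("chi2", "ks"),
                            criterion = c("aic", "bic"),
                            prune_threshold = 0, dt = 1, seed = 1L) {
  test <- match.arg(test)
  criterion <- match.arg(criterion)
  if (!(q > 0 && q < 0.5)) fc_config_error("q must lie in (0, 0.5)")
  if (k_max < 1) fc_config_error("k_max must be >= 1")
  if (!is.null(k_fixed) && k_fixed < 1) fc_config_error("k_fixed must be >= 1")
  if (!(alpha > 0 && alpha < 1)) fc_config_error("alpha must lie in (0, 1)")
  if (!is.null(max_length) && max_length < 1) fc_config_error("max_length must be >= 1")
  if (prune_threshold < 0 || prune_threshold >= 1)
    fc_config_error("prune_threshold must lie in [0, 1)")
  if (dt <= 0) fc_config_error("dt must be > 0")
  structure(list(q = q, k_max = as.integer(k_max),
                 k_fixed = if (is.null(k_fixed)) NULL else as.integer(k_fixed),
                 alpha = alpha,
                 max_length = if (is.null(max_length)) NULL else as.integer(max_length),
                 test = test, criterion = criterion,
                 prune_threshold = prune_threshold, dt = dt,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Infer a causal-state machine from a raw trace
#'
#' Runs the complete inference pipeline: Gaussian mixture fit with AIC
#' selection, certainty partition at the `q` quantiles, probability-mass
#' equalisation, symbolisation with the null symbol, null-aware suffix
#' counting, causal-state splitting, determinisation, restriction to the
#' recurrent class, optional pruning, and attachment of the fitted
#' emissions so the result is a generative model of the raw signal.
#'
#' @param trace a [fret_trace()] or numeric vector.
#' @param config a [pipeline_config()].
#' @return An object of class `cssr_fit`: list with `machine` (the final
#'   [csm()]), `mixture`, `partition`, `symbols`, `counts`, `states`
#'   (causal-state partition of histories), `max_length` and `config`.
#' @examples
#' sim <- simulate_trace(two_state_machine(), 1500, seed = 1, dt = 0.041)
#' fit <- infer_machine(sim$trace, pipeline_config(dt = 0.041, max_length = 2))
#' fit$machine
#' @export
infer_machine <- function(trace, config = pipeline_config()) {
  trace <- as_trace(trace, dt = config$dt)
  if (length(trace$values) < 10)
    fc_data_error("trace too short for inference")
  disc <- discretize_trace(trace, config)
  mixture <- disc$mixture
  partition <- disc$partition
  symbols <- disc$symbols
  counts <- disc$counts
  L <- disc$max_length
  cfg <- cssr_config(alpha = config$alpha, max_length = L, test = config$test,
                     prune_threshold = config$prune_threshold,
                     seed = config$seed)
  states <- infer_causal_states(counts, cfg)
  machine <- remove_transients(determinize(states, counts))
  if (config$prune_threshold > 0)
    machine <- prune_transitions(machine, config$prune_threshold)
  machine <- attach_emissions(machine, mixture)
  structure(list(machine = machine, mixture = mixture, partition = partition,
                 symbols = symbols, counts = counts, states = states,
                 max_length = L, config = config),
            class = "cssr_fit")
}

# Select a mixture and carry it through partition construction,
# equalisation, symbolisation and window counting.  A candidate mixture is
# unusable when it admits no valid partition (nested or fully overlapped
# quantile intervals -- the signature of an overfitted spurious component)
# or when its discretisation leaves too little certain data to count
# subsequences; selection then falls back to the next-best candidate by
# the information criterion.  Only if every candidate fails does the first
# error propagate.
discretize_trace <- function(trace, config) {
  try_one <- function(mixture) {
    partition <- equalize_partition(build_partition(mixture, q = config$q), mixture)
    symbols <- symbolize(trace, partition)
    L <- if (is.null(config$max_length))
      suggest_max_length(sum(!is.na(symbols$symbols)), symbols$k)
    else config$max_length
    counts <- count_windows(symbols, max_length = L)
    list(mixture = mixture, partition = partition, symbols = symbols,
         counts = counts, max_length = L)
  }
  if (!is.null(config$k_fixed))
    return(try_one(fit_mixture(trace$values, config$k_fixed, seed = config$seed)))
  best <- select_mixture(trace$values, k_max = config$k_max, seed = config$seed,
                         criterion = config$criterion)
  cand <- attr(best, "candidates")
  score <- if (config$criterion == "aic") cand$aic else cand$bic
  err <- NULL
  for (k in cand$k[order(score)]) {
    res <- tryCatch(try_one(fit_mixture(trace$values, k, seed = config$seed)),
                    fretcssr_partition_error = function(e) e,
                    fretcssr_data_error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (is.null(err)) err <- res
  }
  stop(err)
}

#' @export
print.cssr_fit <- function(x, ...) {
  cat(sprintf("Causal-state reconstruction (K = %d levels, L_max = %d, alpha = %g)\n",
              nrow(x$mixture$components), x$max_length, x$config$alpha))
  cat(sprintf("  %d/%d bins certain (%.1f%%)\n",
              sum(!is.na(x$symbols$symbols)), x$symbols$source_length,
              100 * mean(!is.na(x$symbols$symbols))))
  print(x$machine)
  invisible(x)
}
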