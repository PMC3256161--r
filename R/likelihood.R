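#' Forward log-likelihood of a trace under a machine
#'
#' Log probability density of the observed values under the machine, with
#' the hidden state marginalised by the forward recursion.  The initial
#' state is distributed according to the stationary distribution (the
#' method assumes stationary dynamics throughout).  Each transition
#' contributes its probability times the Gaussian density of its symbol at
#' the observed value.  The recursion is rescaled at every step, so results
#' stay finite for very long traces.
#'
#' @param m a [csm()] with emissions.
#' @param trace a [fret_trace()] or numeric vector.
#' @return Log-likelihood in nats; `0` for an empty trace.
#' @export
forward_loglik <- function(m, trace) {
  trace <- as_trace(trace)
  x <- trace$values
  if (length(x) == 0) return(0)
  validate_csm(m)
  M <- symbol_matrices(m)
  em <- m$emissions[match(m$alphabet, m$emissions$symbol), ]
  alpha <- stationary_distribution(m)[m$states]
  S <- length(m$states)
  ll <- 0
  for (t in seq_along(x)) {
    dens <- stats::dnorm(x[t], em$mean, em$sd)
    a_new <- numeric(S)
    for (a in seq_along(M)) {
      if (!is.na(dens[a]) && dens[a] > 0)
        a_new <- a_new + as.vector(alpha %*% M[[a]]) * dens[a]
    }
    ct <- sum(a_new)
    if (ct <= 0 || !is.finite(ct)) {
      # all paths annihilated (observation impossibly far in the tails):
      # fall back to log of the smallest representable mass
      return(-.Machine$double.xmax)
    }
    ll <- ll + log(ct)
    alpha <- a_new / ct
  }
  ll
}

#' Most probable hidden state path (Viterbi)
#'
#' Jointly most probable state sequence given the observed trace, with the
#' initial state marginal taken as the stationary distribution.  Ties are
#' broken deterministically towards the lowest state id (in the machine's
#' state ordering).
#'
#' @inheritParams forward_loglik
#' @return Character vector of state ids, one per observation (the state
#'   occupied after each emission), with attribute `logprob` holding the
#'   joint log probability of the returned path.
#' @export
viterbi_path <- function(m, trace) {
  trace <- as_trace(trace)
  x <- trace$values
  validate_csm(m)
  if (length(x) == 0) return(character(0))
  S <- length(m$states)
  tr <- m$transitions[m$transitions$p > 0, , drop = FALSE]
  fi <- match(tr$from, m$states)
  ti <- match(tr$to, m$states)
  ai <- match(tr$symbol, m$alphabet)
  lp <- log(tr$p)
  em <- m$emissions[match(m$alphabet, m$emissions$symbol), ]
  n <- length(x)
  delta <- log(stationary_distribution(m)[m$states])
  back <- matrix(NA_integer_, n, S)
  for (t in seq_len(n)) {
    ldens <- stats::dnorm(x[t], em$mean, em$sd, log = TRUE)
    cand <- delta[fi] + lp + ldens[ai]
    d_new <- rep(-Inf, S)
    b_new <- rep(NA_integer_, S)
    # iterate in source-state order so ties keep the lowest predecessor
    ord <- order(ti, fi)
    for (idx in ord) {
      j <- ti[idx]
      if (cand[idx] > d_new[j]) {
        d_new[j] <- cand[idx]
        b_new[j] <- fi[idx]
      }
    }
    delta <- d_new
    back[t, ] <- b_new
    if (all(!is.finite(delta))) fc_data_error("no admissible state path (zero likelihood)")
  }
  path <- integer(n)
  path[n] <- which.max(delta)  # which.max takes the first (lowest id) on ties
  if (n > 1) for (t in n:2) path[t - 1] <- back[t, path[t]]
  structure(m$states[path], logprob = max(delta))
}

#' Rabiner model distance between two machines on one trace
#'
#' Per-sample difference of the log-likelihoods of the same observation
#' sequence under a generating and an inferred model,
#' `D = (log P(O | gen) - log P(O | inf)) / T`, in nats per sample.  Zero
#' for models with identical statistical properties; the sign is preserved
#' (an inferred model may fit the particular trace better than the
#' generator, giving a negative distance).
#'
#' @param gen,inf [csm()] objects with emissions.
#' @param trace a [fret_trace()] or numeric vector (non-empty).
#' @return An object of class `model_distance`: list with `distance`
#'   (nats/sample), `loglik_gen`, `loglik_inf` and `length`.
#' @export
model_distance <- function(gen, inf, trace) {
  trace <- as_trace(trace)
  if (length(trace$values) == 0) fc_data_error("model distance needs a non-empty trace")
  lg <- forward_loglik(gen, trace)
  li <- forward_loglik(inf, trace)
  structure(list(distance = (lg - li) / length(trace$values),
                 loglik_gen = lg, loglik_inf = li,
                 length = length(trace$values)),
            class = "model_distance")
}

#' @export
print.model_distance <- function(x, ...) {
  cat(sprintf("Model distance: %.6g nats/sample over %d samples\n",
              x$distance, x$length))
  cat(sprintf("  log P(O|gen) = %.6g, log P(O|inf) = %.6g\n",
              x$loglik_gen, x$loglik_inf))
  invisible(x)
}
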