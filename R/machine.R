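#' Causal-state machine (symbol-emitting unifilar HMM)
#'
#' A causal-state machine is a hidden Markov model in Mealy form: each
#' transition is labelled with a symbol from a finite alphabet, and the
#' machine is *unifilar* (deterministic): from any state, the emitted symbol
#' uniquely determines the successor state.  Optionally each symbol carries a
#' Gaussian observation density, in which case the machine generates
#' continuous traces by sampling the transition symbol's Gaussian at every
#' step -- the standard picture for single-molecule FRET trajectories, where
#' the symbols are FRET levels blurred by measurement noise.
#'
#' @param transitions data frame with columns `from`, `symbol`, `to`, `p`
#'   and optionally `count`.  `symbol` must be integer codes `0..K-1`;
#'   `from`/`to` are state identifiers (coerced to character).
#' @param emissions optional data frame with columns `symbol`, `mean`, `sd`
#'   (and optionally `weight`), one row per alphabet symbol.
#' @param suffixes optional named list mapping each state to the character
#'   vector of history suffixes it represents (empty for hand-built
#'   generators).
#' @param states optional character vector fixing the state ordering;
#'   defaults to sorted unique states in `transitions`.
#' @param alphabet optional integer vector `0..K-1` fixing the alphabet
#'   size; defaults to `0..max(symbol)` over the transitions.  Supply it
#'   when a symbol of the discretisation never appears on a surviving
#'   transition.
#' @param validate check machine invariants (default `TRUE`).
#'
#' @return An object of class `csm`: a list with elements `states`,
#'   `alphabet` (integer vector `0..K-1`), `transitions`, `emissions` and
#'   `suffixes`.
#'
#' @examples
#' m <- csm(data.frame(from = c("L", "L", "H", "H"),
#'                     symbol = c(0L, 1L, 1L, 0L),
#'                     to = c("L", "H", "H", "L"),
#'                     p = c(0.9, 0.1, 0.9, 0.1)),
#'          emissions = data.frame(symbol = 0:1, mean = c(0.3, 0.7), sd = 0.1))
#' stationary_distribution(m)
#' @export
csm <- function(transitions, emissions = NULL, suffixes = NULL,
                states = NULL, alphabet = NULL, validate = TRUE) {
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  need <- c("from", "symbol", "to", "p")
  if (!all(need %in% names(transitions)))
    fc_config_error("transitions must have columns from, symbol, to, p")
  transitions$from <- as.character(transitions$from)
  transitions$to <- as.character(transitions$to)
  transitions$symbol <- as.integer(transitions$symbol)
  transitions$p <- as.numeric(transitions$p)
  transitions$count <- if (is.null(transitions$count)) NA_real_
                       else as.numeric(transitions$count)
  if (is.null(states)) states <- sort(unique(c(transitions$from, transitions$to)))
  if (is.null(alphabet)) alphabet <- seq_len(max(transitions$symbol) + 1L) - 1L
  alphabet <- as.integer(alphabet)
  if (!is.null(emissions)) {
    emissions <- as.data.frame(emissions, stringsAsFactors = FALSE)
    emissions$symbol <- as.integer(emissions$symbol)
    emissions <- emissions[order(emissions$symbol), , drop = FALSE]
    rownames(emissions) <- NULL
  }
  m <- structure(list(states = states, alphabet = alphabet,
                      transitions = transitions, emissions = emissions,
                      suffixes = suffixes),
                 class = "csm")
  if (validate) validate_csm(m)
  m
}

#' Validate causal-state machine invariants
#'
#' Checks that probabilities lie in `[0, 1]`, every state's outgoing
#' probabilities sum to one (within `1e-9`), and the machine is unifilar
#' (no `(state, symbol)` pair has two successors).  Reachability is *not*
#' checked here; machines straight out of state splitting may still contain
#' transient states (see [remove_transients()]).
#'
#' @param m a [csm()] object.
#' @return `m`, invisibly.
#' @export
validate_csm <- function(m) {
  tr <- m$transitions
  if (any(tr$p < -1e-12 | tr$p > 1 + 1e-12))
    fc_config_error("transition probabilities must lie in [0, 1]")
  if (!all(tr$from %in% m$states) || !all(tr$to %in% m$states))
    fc_config_error("transition endpoints must be listed states")
  sums <- tapply(tr$p, tr$from, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad))
    fc_config_error(sprintf("outgoing probabilities of state(s) %s do not sum to 1",
                            paste(bad, collapse = ", ")))
  if (!all(m$states %in% tr$from))
    fc_config_error("every state needs at least one outgoing transition")
  key <- paste(tr$from, tr$symbol)
  if (anyDuplicated(key))
    fc_config_error("machine is not unifilar: duplicated (state, symbol) pair")
  if (!is.null(m$emissions)) {
    if (any(m$emissions$sd <= 0)) fc_config_error("emission sd must be > 0")
  }
  invisible(m)
}

#' @export
print.csm <- function(x, ...) {
  cat(sprintf("Causal-state machine: %d state(s), alphabet size %d%s\n",
              length(x$states), length(x$alphabet),
              if (is.null(x$emissions)) "" else ", Gaussian emissions"))
  tr <- x$transitions[order(x$transitions$from, x$transitions$symbol), ]
  for (i in seq_len(nrow(tr)))
    cat(sprintf("  %s --%d (p=%.4g)--> %s\n",
                tr$from[i], tr$symbol[i], tr$p[i], tr$to[i]))
  if (!is.null(x$emissions)) {
    for (i in seq_len(nrow(x$emissions)))
      cat(sprintf("  symbol %d ~ N(%.4g, %.4g^2)\n", x$emissions$symbol[i],
                  x$emissions$mean[i], x$emissions$sd[i]))
  }
  invisible(x)
}

# State-to-state transition matrix (symbols marginalised out).
state_matrix <- function(m) {
  S <- length(m$states)
  P <- matrix(0, S, S, dimnames = list(m$states, m$states))
  tr <- m$transitions
  for (i in seq_len(nrow(tr)))
    P[tr$from[i], tr$to[i]] <- P[tr$from[i], tr$to[i]] + tr$p[i]
  P
}

# One dense S x S matrix per symbol; M[[a+1]][i, j] = p(i --a--> j).
symbol_matrices <- function(m) {
  S <- length(m$states)
  out <- lapply(m$alphabet, function(a) {
    M <- matrix(0, S, S, dimnames = list(m$states, m$states))
    tr <- m$transitions[m$transitions$symbol == a, , drop = FALSE]
    if (nrow(tr)) M[cbind(match(tr$from, m$states), match(tr$to, m$states))] <- tr$p
    M
  })
  names(out) <- as.character(m$alphabet)
  out
}

strong_components <- function(m) {
  tr <- m$transitions[m$transitions$p > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(tr[, c("from", "to")], directed = TRUE,
                                     vertices = data.frame(name = m$states))
  igraph::components(g, mode = "strong")
}

#' Stationary distribution over machine states
#'
#' Left fixed point of the state-to-state transition matrix.  The machine
#' must consist of a single recurrent class (strongly connected on its
#' positive-probability transitions); use [remove_transients()] first on raw
#' reconstruction output.
#'
#' @param m a [csm()] object.
#' @return Named numeric vector over states; non-negative, sums to one.
#' @export
stationary_distribution <- function(m) {
  comp <- strong_components(m)
  if (comp$no > 1) {
    sizes <- split(m$states, comp$membership)
    fc_inference_error(sprintf(
      "machine is reducible; strongly connected classes: %s",
      paste(vapply(sizes, function(s) paste0("{", paste(s, collapse = ","), "}"),
                   character(1)), collapse = " ")))
  }
  P <- state_matrix(m)
  S <- nrow(P)
  if (S == 1) return(stats::setNames(1, m$states))
  A <- t(P) - diag(S)
  A[S, ] <- 1
  b <- c(rep(0, S - 1), 1)
  pi <- solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  stats::setNames(pi / sum(pi), m$states)
}

#' Statistical complexity of a machine
#'
#' Shannon entropy (base 2) of the stationary distribution over causal
#' states: the average information the machine stores about the past in
#' order to predict the future.
#'
#' @param m a [csm()] object with a single recurrent class.
#' @return Entropy in bits.
#' @export
statistical_complexity <- function(m) {
  p <- stationary_distribution(m)
  p <- p[p > 0]
  -sum(p * log2(p))
}
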