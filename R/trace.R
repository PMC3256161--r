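#' Single-molecule trace
#'
#' A real-valued, uniformly sampled time series (e.g. a FRET-efficiency
#' trajectory) together with its sampling interval.
#'
#' @param values numeric vector of signal levels.
#' @param dt sampling interval in seconds (> 0).
#' @return An object of class `fret_trace` with elements `values` and `dt`.
#' @export
fret_trace <- function(values, dt = 1) {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1 || is.na(dt) || dt <= 0)
    fc_config_error("dt must be a single positive number (seconds)")
  if (anyNA(values)) fc_data_error("trace values must not contain NA")
  structure(list(values = values, dt = dt), class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("Trace: %d samples, dt = %g s (%.4g s total)\n",
              length(x$values), x$dt, length(x$values) * x$dt))
  invisible(x)
}

#' @export
length.fret_trace <- function(x) length(x$values)

as_trace <- function(x, dt = 1) {
  if (inherits(x, "fret_trace")) x else fret_trace(x, dt)
}

#' Simulate a trace from a causal-state machine
#'
#' Runs the machine from a stationary start state.  At each time step a
#' transition is drawn from the current state according to its
#' probabilities, the transition's symbol Gaussian is sampled for the
#' observed value, and the machine advances to the successor state.
#'
#' @param m a [csm()] with emissions for every reachable symbol.
#' @param n number of samples (>= 1).
#' @param seed integer seed; identical seeds give identical output.
#' @param dt sampling interval attached to the returned trace (seconds).
#' @return A list with components `trace` (a [fret_trace()]), `states`
#'   (hidden state after each emission, length `n`) and `symbols` (emitted
#'   symbol path, integer vector of length `n`).
#' @examples
#' m <- two_state_machine()
#' sim <- simulate_trace(m, 1500, seed = 1, dt = 0.041)
#' hist(sim$trace$values, breaks = 40)
#' @export
simulate_trace <- function(m, n, seed = 1L, dt = 1) {
  validate_csm(m)
  if (n < 1) fc_config_error("n must be >= 1")
  used <- sort(unique(m$transitions$symbol[m$transitions$p > 0]))
  if (is.null(m$emissions) || !all(used %in% m$emissions$symbol))
    fc_config_error("machine lacks an emission for a reachable symbol")
  set.seed(seed)
  start <- stationary_distribution(m)
  # per-state transition tables for fast repeated sampling
  tabs <- split(m$transitions[m$transitions$p > 0, ], m$transitions$from[m$transitions$p > 0])
  s <- sample(m$states, 1, prob = start[m$states])
  syms <- integer(n)
  states <- character(n)
  for (t in seq_len(n)) {
    tab <- tabs[[s]]
    i <- if (nrow(tab) == 1) 1L else sample.int(nrow(tab), 1, prob = tab$p)
    syms[t] <- tab$symbol[i]
    s <- tab$to[i]
    states[t] <- s
  }
  em <- m$emissions[match(syms, m$emissions$symbol), ]
  values <- stats::rnorm(n, mean = em$mean, sd = em$sd)
  list(trace = fret_trace(values, dt), states = states, symbols = syms)
}
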