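#' Transition rates from per-bin probabilities
#'
#' Converts the machine's per-bin transition probabilities into physical
#' rates by dividing by the sampling interval: a transition taken with
#' probability `p` per bin of `dt` seconds corresponds to a rate of
#' `p / dt` per second.  Self-loops (staying in a state) are not rates and
#' are excluded from the report.
#'
#' @param m a [csm()].
#' @param dt sampling interval in seconds (> 0).
#' @return Data frame with columns `from`, `to`, `symbol`, `probability`,
#'   `rate` (s^-1) and `dt`.
#' @export
transition_rates <- function(m, dt) {
  if (dt <= 0) fc_config_error("dt must be > 0")
  tr <- m$transitions[m$transitions$from != m$transitions$to, , drop = FALSE]
  out <- data.frame(from = tr$from, to = tr$to, symbol = tr$symbol,
                    probability = tr$p, rate = tr$p / dt, dt = dt)
  rownames(out) <- NULL
  out[order(out$from, out$to), ]
}

#' Aggregate per-trace rates in log space
#'
#' Rates estimated from single-molecule traces scatter multiplicatively,
#' so multi-trace summaries are formed by taking logs, averaging, and
#' exponentiating: the geometric mean, with the log-space standard
#' deviation as the spread.
#'
#' @param rates positive numeric vector of per-trace rates for one
#'   transition, or a data frame with columns `label` and `rate` for
#'   several transitions at once.
#' @return Data frame with columns `label`, `geometric_mean_rate`,
#'   `log_sd` (0 when only one trace contributes) and `n_traces`.
#' @export
aggregate_rates <- function(rates) {
  if (is.data.frame(rates)) {
    if (!all(c("label", "rate") %in% names(rates)))
      fc_config_error("rate data frame needs columns label and rate")
    parts <- split(rates$rate, rates$label)
    out <- do.call(rbind, lapply(names(parts), function(lab) {
      s <- summarise_rates(parts[[lab]], lab)
      s
    }))
    rownames(out) <- NULL
    return(out)
  }
  summarise_rates(as.numeric(rates), label = "rate")
}

summarise_rates <- function(r, label) {
  if (any(!is.finite(r) | r <= 0)) {
    bad <- which(!is.finite(r) | r <= 0)
    fc_data_error(sprintf("non-positive rate in trace(s) %s for transition %s",
                          paste(bad, collapse = ", "), label))
  }
  lr <- log(r)
  data.frame(label = label,
             geometric_mean_rate = exp(mean(lr)),
             log_sd = if (length(r) > 1) stats::sd(lr) else 0,
             n_traces = length(r))
}

#' Dwell times from a state path
#'
#' Run-length encodes a hidden state path (e.g. the Viterbi trajectory)
#' into per-state dwell durations.  The first and last runs are censored
#' (the entry into the first and the exit from the last state were not
#' observed) and are excluded from rate fitting.
#'
#' @param path character or integer vector of states, one per bin.
#' @param dt bin width in seconds.
#' @return Named list, one element per state: list with `durations`
#'   (uncensored dwells, seconds), `censored` (censored dwell durations),
#'   and `fitted_rate` (`1 / mean(durations)`, `NA` when no uncensored
#'   dwell exists).
#' @export
dwell_times <- function(path, dt) {
  if (!length(path)) fc_data_error("empty state path")
  if (dt <= 0) fc_config_error("dt must be > 0")
  r <- rle(as.character(path))
  n <- length(r$lengths)
  censored <- rep(FALSE, n)
  censored[1] <- TRUE
  censored[n] <- TRUE
  out <- lapply(sort(unique(r$values)), function(s) {
    sel <- r$values == s
    dur <- r$lengths[sel & !censored] * dt
    cen <- r$lengths[sel & censored] * dt
    list(durations = dur, censored = cen,
         fitted_rate = if (length(dur)) 1 / mean(dur) else NA_real_)
  })
  names(out) <- sort(unique(r$values))
  out
}

#' Exponential fit to dwell-time distributions
#'
#' Maximum-likelihood exponential rate for a set of uncensored dwell
#' times (`rate = 1 / mean`), together with histogram bins and the fitted
#' density curve for overlay plots.
#'
#' @param dwells numeric vector of dwell durations (seconds), or one
#'   element of a [dwell_times()] result.
#' @param breaks passed to [hist()] (default `"Sturges"`).
#' @return List with `rate` (s^-1), `n`, `histogram` (data frame `mid`,
#'   `density`, `counts`) and `curve` (data frame `t`, `density`).
#' @export
fit_exponential_dwell <- function(dwells, breaks = "Sturges") {
  if (is.list(dwells) && !is.null(dwells$durations)) dwells <- dwells$durations
  dwells <- as.numeric(dwells)
  if (length(dwells) < 5)
    fc_data_error("need at least 5 uncensored dwell times to fit")
  rate <- 1 / mean(dwells)
  h <- graphics::hist(dwells, breaks = breaks, plot = FALSE)
  tt <- seq(0, max(dwells), length.out = 200)
  list(rate = rate, n = length(dwells),
       histogram = data.frame(mid = h$mids, density = h$density,
                              counts = h$counts),
       curve = data.frame(t = tt, density = rate * exp(-rate * tt)))
}

#' Split-half stationarity check of a symbol sequence
#'
#' The reconstruction assumes the transition statistics are stationary;
#' spectra whose levels drift across the partition violate this and must
#' be rejected, not repaired.  This diagnostic splits the symbol sequence
#' in half and compares, between halves, (i) the marginal certain-symbol
#' frequencies and (ii) the next-symbol distribution following each
#' single-symbol history, using the same equivalence test as the
#' reconstruction.
#'
#' The verdict rests on the conditional (next-symbol) comparisons: those
#' counts are independent draws given the history, so the test holds its
#' nominal level.  The marginal occupancy of a slowly exchanging system
#' fluctuates far beyond multinomial sampling error even under perfect
#' stationarity (neighbouring bins are strongly correlated), so the
#' marginal comparison is reported for inspection but does not by itself
#' fail the check.
#'
#' @param symbols a `symbol_sequence` (or integer vector with `NA` nulls).
#' @param alpha significance level.
#' @param method `"chi2"` or `"ks"`.
#' @return List of class `stationarity_report` with `status` (`"pass"`,
#'   `"fail"` or `"inconclusive"`) and `comparisons` (data frame of
#'   per-comparison p-values).
#' @export
stationarity_check <- function(symbols, alpha = 0.05, method = c("chi2", "ks")) {
  method <- match.arg(method)
  s <- if (inherits(symbols, "symbol_sequence")) symbols$symbols else as.integer(symbols)
  k <- if (inherits(symbols, "symbol_sequence")) symbols$k else max(s, na.rm = TRUE) + 1L
  n <- length(s)
  half1 <- s[seq_len(n %/% 2)]
  half2 <- s[(n %/% 2 + 1):n]
  c1 <- tryCatch(count_windows(half1, 1L, k = k), error = function(e) NULL)
  c2 <- tryCatch(count_windows(half2, 1L, k = k), error = function(e) NULL)
  if (is.null(c1) || is.null(c2))
    return(structure(list(status = "inconclusive",
                          comparisons = data.frame()),
                     class = "stationarity_report"))
  rows <- list()
  marg <- test_equivalence(c1$counts[1, ], c2$counts[1, ], alpha, method)
  rows[[1]] <- data.frame(comparison = "marginal", p_value = marg$p_value,
                          distinct = marg$distinct, in_verdict = FALSE)
  for (a in as.character(0:(k - 1L))) {
    if (!(a %in% rownames(c1$counts)) || !(a %in% rownames(c2$counts))) next
    if (c1$totals[a] == 0 || c2$totals[a] == 0) next
    r <- test_equivalence(c1$counts[a, ], c2$counts[a, ], alpha, method)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = sprintf("after '%s'", a), p_value = r$p_value,
      distinct = r$distinct, in_verdict = TRUE)
  }
  comparisons <- do.call(rbind, rows)
  verdict <- comparisons$distinct[comparisons$in_verdict]
  status <- if (!length(verdict)) "inconclusive"
            else if (any(verdict)) "fail" else "pass"
  structure(list(status = status, comparisons = comparisons),
            class = "stationarity_report")
}

#' @export
print.stationarity_report <- function(x, ...) {
  cat(sprintf("Stationarity check: %s\n", x$status))
  if (nrow(x$comparisons)) print(x$comparisons, digits = 4)
  invisible(x)
}
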