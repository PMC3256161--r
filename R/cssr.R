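# Token for the empty history.  R's name matching never matches an empty
# string, so "" cannot be used as a rowname/list key.
EMPTY_HISTORY <- "."

# Length in symbols (the empty-history token has length 0).
hist_len <- function(h) ifelse(h == EMPTY_HISTORY, 0L, nchar(h))

# Parent (drop the oldest symbol) of a non-empty history string.
hist_parent <- function(h) {
  p <- substring(h, 2L)
  ifelse(p == "", EMPTY_HISTORY, p)
}

# Append symbol a to history h, truncating from the left to max_length.
hist_extend <- function(h, a, max_length) {
  s <- paste0(if (h == EMPTY_HISTORY) "" else h, a)
  if (nchar(s) > max_length) s <- substring(s, nchar(s) - max_length + 1L)
  s
}

#' Count null-free subsequence windows
#'
#' Builds the suffix statistics the reconstruction works from: for every
#' history of length `0..max_length` over the *certain* alphabet, the
#' counts of each next symbol.  Counts for a length-`l` history come only
#' from windows of `l + 1` consecutive non-null symbols; any window that
#' touches a null symbol is discarded whole (the flanks are never spliced
#' together, which would fabricate transitions across uncertain gaps).
#'
#' @param symbols a [symbolize()] result, or an integer vector over
#'   `0..k-1` with `NA` for the null symbol.
#' @param max_length longest history length to count (>= 1).
#' @param k alphabet size (inferred when `symbols` is a `symbol_sequence`).
#' @return An object of class `suffix_counts`: list with `counts` (matrix:
#'   one row per observed history, one column per symbol), `totals` (row
#'   sums), `max_length`, `k`, `n_certain` (number of non-null bins) and
#'   `n_windows` (usable windows per window length `1..max_length + 1`).
#' @export
count_windows <- function(symbols, max_length, k = NULL) {
  if (inherits(symbols, "symbol_sequence")) {
    k <- symbols$k
    s <- symbols$symbols
  } else {
    s <- as.integer(symbols)
    if (is.null(k)) k <- max(s, na.rm = TRUE) + 1L
  }
  max_length <- as.integer(max_length)
  if (max_length < 1) fc_config_error("max_length must be >= 1")
  if (k > 10) fc_config_error("alphabets larger than 10 symbols are not supported")
  n <- length(s)
  bad <- cumsum(is.na(s))
  counts <- list()
  n_windows <- integer(max_length + 1L)
  for (len in 0:max_length) {
    w <- len + 1L                          # window length: history + next symbol
    if (n < w) break
    starts <- seq_len(n - w + 1L)
    clean <- (bad[starts + w - 1L] - c(0, bad)[starts]) == 0
    starts <- starts[clean]
    n_windows[w] <- length(starts)
    if (!length(starts)) next
    h <- if (len == 0) rep(EMPTY_HISTORY, length(starts)) else {
      cols <- lapply(0:(len - 1L), function(j) s[starts + j])
      do.call(paste0, cols)
    }
    nxt <- s[starts + len]
    tab <- table(factor(h, levels = sort(unique(h))),
                 factor(nxt, levels = 0:(k - 1L)))
    counts[[length(counts) + 1L]] <- as.matrix(unclass(tab))
  }
  if (length(counts) == 0 || n_windows[1] == 0)
    fc_data_error("insufficient certain data: no usable windows")
  if (max_length >= 1 && n_windows[2] == 0)
    fc_data_error("insufficient certain data: no adjacent pair of certain symbols")
  mat <- do.call(rbind, counts)
  colnames(mat) <- as.character(0:(k - 1L))
  structure(list(counts = mat, totals = rowSums(mat),
                 max_length = max_length, k = as.integer(k),
                 n_certain = sum(!is.na(s)), n_windows = n_windows),
            class = "suffix_counts")
}

#' @export
print.suffix_counts <- function(x, ...) {
  cat(sprintf("Suffix counts: %d histories (max length %d), alphabet %d, %d certain bins\n",
              nrow(x$counts), x$max_length, x$k, x$n_certain))
  invisible(x)
}

#' Suggest a maximum history length
#'
#' The statistical test that drives state splitting needs enough
#' occurrences of each candidate history to see its next-symbol
#' distribution.  This heuristic returns the largest `L` such that the
#' expected count per length-`L` history, `n_certain / k^L`, is at least
#' `min_expected` (default 25), and always at least 1.
#'
#' @param n_certain number of certain (non-null) symbols available.
#' @param k alphabet size.
#' @param min_expected required expected count per history (default 25).
#' @param cap upper bound on the suggestion (default 16; relevant for
#'   `k = 1`, where every history length is observable).
#' @return Integer `L >= 1`.
#' @export
suggest_max_length <- function(n_certain, k, min_expected = 25, cap = 16L) {
  if (k < 1) fc_config_error("k must be >= 1")
  if (k == 1) return(min(cap, max(1L, as.integer(floor(n_certain / min_expected)))))
  L <- floor(log(n_certain / min_expected) / log(k))
  as.integer(min(cap, max(1, L)))
}

#' Test equivalence of two next-symbol distributions
#'
#' Two-sample chi-squared homogeneity test on next-symbol count vectors
#' (the default), used both to decide whether a history belongs to an
#' existing causal state and in the stationarity diagnostics.  Cells whose
#' smallest expected count under homogeneity falls below 1 are merged into
#' a single pooled cell before the statistic is computed.  A two-sample
#' Kolmogorov-Smirnov variant on the symbol CDF is available via `method`.
#'
#' @param a,b non-negative count vectors of equal length (both with
#'   positive totals).
#' @param alpha significance level for the `distinct` verdict.
#' @param method `"chi2"` (default) or `"ks"`.
#' @return List with `p_value`, `statistic`, `df` and `distinct`
#'   (`TRUE` iff `p_value < alpha`).
#' @export
test_equivalence <- function(a, b, alpha = 0.05, method = c("chi2", "ks")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) fc_config_error("count vectors must have equal length")
  na <- sum(a); nb <- sum(b)
  if (na <= 0 || nb <= 0) fc_config_error("both count totals must be positive")
  if (method == "ks") return(ks_equivalence(a, b, alpha))
  pooled <- a + b
  keep <- pooled > 0
  a <- a[keep]; b <- b[keep]; pooled <- pooled[keep]
  N <- na + nb
  # merge cells whose minimum expected count (smaller row) is below 1
  low <- min(na, nb) * pooled / N < 1
  if (any(low) && sum(!low) >= 1) {
    a <- c(a[!low], sum(a[low]))
    b <- c(b[!low], sum(b[low]))
  } else if (all(low)) {
    a <- sum(a); b <- sum(b)
  }
  C <- length(a)
  if (C < 2)
    return(list(p_value = 1, statistic = 0, df = 0L, distinct = FALSE))
  O <- rbind(a, b)
  E <- outer(c(na, nb), (a + b) / N)
  dev <- abs(O - E)
  # Yates continuity correction on 2x2 tables, as in stats::chisq.test
  if (C == 2L) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  df <- C - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(p_value = p, statistic = stat, df = df, distinct = p < alpha)
}

ks_equivalence <- function(a, b, alpha) {
  na <- sum(a); nb <- sum(b)
  D <- max(abs(cumsum(a) / na - cumsum(b) / nb))
  ne <- sqrt(na * nb / (na + nb))
  lambda <- (ne + 0.12 + 0.11 / ne) * D
  # the asymptotic series is only valid away from zero; tiny lambda means
  # the samples are indistinguishable
  p <- if (lambda < 0.3) 1 else {
    j <- 1:100
    min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
  }
  list(p_value = p, statistic = D, df = NA_integer_, distinct = p < alpha)
}

#' Reconstruction configuration
#'
#' Parameters of the causal-state reconstruction.
#'
#' @param alpha significance level of the state-splitting test (default
#'   0.05).
#' @param max_length longest history length; `NULL` means choose with
#'   [suggest_max_length()].
#' @param test `"chi2"` or `"ks"`.
#' @param prune_threshold transitions with probability below this are
#'   pruned from the final machine (default 0 = off).
#' @param seed integer seed (the mixture fit consumes it; reconstruction
#'   itself is deterministic).
#' @return A list of class `cssr_config`.
#' @export
cssr_config <- function(alpha = 0.05, max_length = NULL,
                        test = c("chi2", "ks"), prune_threshold = 0,
                        seed = 1L) {
  test <- match.arg(test)
  if (!(alpha > 0 && alpha < 1)) fc_config_error("alpha must lie in (0, 1)")
  if (!is.null(max_length) && max_length < 1) fc_config_error("max_length must be >= 1")
  if (prune_threshold < 0 || prune_threshold >= 1)
    fc_config_error("prune_threshold must lie in [0, 1)")
  structure(list(alpha = alpha, max_length = max_length, test = test,
                 prune_threshold = prune_threshold, seed = as.integer(seed)),
            class = "cssr_config")
}

# Pooled next-symbol counts of a state.  Members that extend another
# member (their suffix chain meets the state) are dropped first: the
# shorter member's counts already contain every window of its extensions,
# so pooling the raw rows would double-count those windows and bias both
# the morph estimate and the significance tests.
# Members of a state that do not extend another member (their suffix chain
# never meets the state).  The shorter member's counts already contain
# every window of its extensions, so pooling over this cover counts each
# observed window exactly once.
minimal_cover <- function(members) {
  keep <- vapply(members, function(h) {
    while (h != EMPTY_HISTORY) {
      h <- hist_parent(h)
      if (h %in% members) return(FALSE)
    }
    TRUE
  }, logical(1))
  members[keep]
}

# Pooled next-symbol counts of a state over its minimal suffix cover;
# raw-row pooling would double-count extension windows and bias both the
# morph estimate and the significance tests.
pooled_counts <- function(counts, members, exclude = NULL) {
  members <- setdiff(members, exclude)
  if (!length(members)) return(NULL)
  colSums(counts$counts[minimal_cover(members), , drop = FALSE])
}

#' Infer causal states from suffix counts
#'
#' The state-splitting phase of the reconstruction.  Starting from a single
#' state holding the empty history, histories are extended one (older)
#' certain symbol at a time up to `max_length`.  Each observed child
#' history is tested against its parent state's pooled next-symbol
#' distribution; if rejected it joins the existing state it is most
#' compatible with (highest test p-value above `alpha`), or founds a new
#' state.  Assignments at each length are re-evaluated until stable, since
#' pooled distributions shift as members move.
#'
#' Histories are enumerated by length and then lexicographically, which
#' fixes all tie-breaking; unobserved histories are never instantiated.
#'
#' @param counts a [count_windows()] result.
#' @param config a [cssr_config()].
#' @return An object of class `causal_states`: list with `states` (list of
#'   character vectors of member histories) and `assignment` (named
#'   integer vector history -> state index).
#' @export
infer_causal_states <- function(counts, config = cssr_config()) {
  L <- counts$max_length
  hists <- rownames(counts$counts)
  usable <- counts$totals > 0
  if (!usable[match(EMPTY_HISTORY, hists)])
    fc_data_error("insufficient certain data: empty history unusable")
  assign <- stats::setNames(1L, EMPTY_HISTORY)
  n_states <- 1L
  lens <- hist_len(hists)
  for (len in 0:(L - 1L)) {
    cand <- hists[lens == len + 1L & usable]
    cand <- cand[hist_parent(cand) %in% names(assign)]
    cand <- sort(cand)
    if (!length(cand)) next
    for (pass in 1:25) {
      changed <- FALSE
      for (child in cand) {
        parent_state <- assign[[hist_parent(child)]]
        cur <- if (child %in% names(assign)) assign[[child]] else NA_integer_
        child_counts <- counts$counts[child, ]
        best <- assign_history(child, child_counts, parent_state, assign,
                               counts, config)
        if (is.na(best)) {          # found no compatible state
          if (!is.na(cur) && sum(assign == cur) == 1L) {
            best <- cur             # already alone in its own state
          } else {
            n_states <- n_states + 1L
            best <- n_states
          }
        }
        if (is.na(cur) || cur != best) {
          assign[child] <- best
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  # compact state ids in order of first appearance
  ids <- unique(unname(assign))
  assign <- stats::setNames(match(assign, ids), names(assign))
  states <- lapply(seq_along(ids), function(i) {
    h <- names(assign)[assign == i]
    h[order(hist_len(h), h)]
  })
  structure(list(states = states, assignment = assign), class = "causal_states")
}

# Decide which state a child history belongs to; NA means "none compatible".
# The child is tested against each state's full pooled distribution; the
# parent pool deliberately retains the parent history (whose counts contain
# the child's occurrences), which makes the parent test conservative -- the
# standard CSSR behaviour that keeps chance splits below the nominal level.
assign_history <- function(child, child_counts, parent_state, assign,
                           counts, config) {
  test1 <- function(members) {
    pc <- pooled_counts(counts, setdiff(members, child))
    if (is.null(pc) || sum(pc) == 0) return(NULL)
    test_equivalence(child_counts, pc, alpha = config$alpha, method = config$test)
  }
  res <- test1(names(assign)[assign == parent_state])
  if (is.null(res) || !res$distinct) return(parent_state)
  other <- setdiff(unique(unname(assign)), parent_state)
  if (length(other)) {
    pvals <- vapply(other, function(s) {
      r <- test1(names(assign)[assign == s])
      if (is.null(r)) -1 else r$p_value
    }, numeric(1))
    if (max(pvals) >= config$alpha) return(other[which.max(pvals)])
  }
  NA_integer_
}

#' @export
print.causal_states <- function(x, ...) {
  cat(sprintf("Causal states: %d\n", length(x$states)))
  for (i in seq_along(x$states)) {
    h <- x$states[[i]]
    h[h == EMPTY_HISTORY] <- "<empty>"
    cat(sprintf("  S%d: %s\n", i, paste(h, collapse = " ")))
  }
  invisible(x)
}

#' Determinise causal states into a unifilar machine
#'
#' Links causal states into a machine by appending each symbol to each
#' member history: the successor of history `h` on symbol `a` is the state
#' containing `h a` (truncated from the left to `max_length`).  States
#' whose member histories disagree about a successor are split into
#' maximal consistent subsets, and the procedure iterates to a fixed point,
#' so the result is unifilar by construction.  Transition probabilities are
#' the pooled relative continuation frequencies of each state's members;
#' a `(state, symbol)` pair with no observed continuation is omitted.
#'
#' @param states a [infer_causal_states()] result (or a list of history
#'   character vectors).
#' @param counts the [count_windows()] the states were built from.
#' @return A [csm()]; typically still containing transient states -- run
#'   [remove_transients()] before stationary analysis.
#' @export
determinize <- function(states, counts) {
  groups <- if (inherits(states, "causal_states")) states$states else states
  if (!length(groups)) fc_inference_error("empty state partition")
  L <- counts$max_length
  hists <- rownames(counts$counts)
  cmat <- counts$counts
  k <- counts$k
  repeat {
    assign <- integer(0)
    for (i in seq_along(groups)) assign[groups[[i]]] <- i
    succ_state <- function(h, a) {
      if (cmat[h, a + 1L] == 0) return(NA_integer_)
      s2 <- hist_extend(h, a, L)
      if (!s2 %in% names(assign)) return(NA_integer_)
      assign[[s2]]
    }
    sig <- lapply(groups, function(members) {
      t(vapply(members, function(h)
        vapply(0:(k - 1L), function(a) succ_state(h, a), integer(1)),
        integer(k)))
    })
    new_groups <- list()
    split_any <- FALSE
    for (i in seq_along(groups)) {
      members <- groups[[i]]
      ord <- order(hist_len(members), members)
      members <- members[ord]
      msig <- sig[[i]][ord, , drop = FALSE]
      sub_members <- list()
      sub_sigs <- list()
      for (j in seq_along(members)) {
        placed <- FALSE
        for (g in seq_along(sub_members)) {
          s1 <- sub_sigs[[g]]; s2 <- msig[j, ]
          conflict <- any(!is.na(s1) & !is.na(s2) & s1 != s2)
          if (!conflict) {
            sub_members[[g]] <- c(sub_members[[g]], members[j])
            s1[is.na(s1)] <- s2[is.na(s1)]
            sub_sigs[[g]] <- s1
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          sub_members[[length(sub_members) + 1L]] <- members[j]
          sub_sigs[[length(sub_sigs) + 1L]] <- msig[j, ]
        }
      }
      if (length(sub_members) > 1) split_any <- TRUE
      new_groups <- c(new_groups, sub_members)
    }
    groups <- new_groups
    if (!split_any) break
  }
  # stable naming: order groups by shortest, then lexicographically
  # smallest member history
  key <- vapply(groups, function(m) {
    m <- m[order(hist_len(m), m)]
    sprintf("%02d%s", hist_len(m[1]), m[1])
  }, character(1))
  groups <- groups[order(key)]
  assign <- integer(0)
  for (i in seq_along(groups)) assign[groups[[i]]] <- i
  ids <- sprintf("S%d", seq_along(groups))
  rows <- list()
  for (i in seq_along(groups)) {
    members <- groups[[i]]
    cover <- minimal_cover(members)
    tot <- sum(counts$totals[cover])
    for (a in 0:(k - 1L)) {
      cnt <- sum(cmat[cover, a + 1L])
      if (cnt == 0) next
      succs <- unique(stats::na.omit(vapply(members, function(h) {
        if (cmat[h, a + 1L] == 0) return(NA_integer_)
        s2 <- hist_extend(h, a, L)
        if (!s2 %in% names(assign)) return(NA_integer_)
        assign[[s2]]
      }, integer(1))))
      if (length(succs) != 1) next   # no (or end-of-data) successor evidence
      rows[[length(rows) + 1L]] <- data.frame(
        from = ids[i], symbol = a, to = ids[succs], p = cnt / tot, count = cnt)
    }
  }
  if (!length(rows)) fc_inference_error("no transitions could be estimated")
  tr <- do.call(rbind, rows)
  # renormalise rows (mass of dropped successor-less continuations)
  for (s in unique(tr$from)) {
    sel <- tr$from == s
    tr$p[sel] <- tr$p[sel] / sum(tr$p[sel])
  }
  suffixes <- stats::setNames(groups, ids)
  csm(tr, suffixes = suffixes, states = ids, alphabet = 0:(k - 1L))
}

#' Restrict a machine to its recurrent class
#'
#' Removes transient states (for example the state holding the empty
#' history, which nothing maps back to) by restricting the machine to its
#' unique terminal strongly connected component and renormalising.  Errors
#' if more than one terminal component exists, since the process would not
#' be ergodic and stationary analysis would be ill-posed.
#'
#' @param m a [csm()].
#' @return The restricted [csm()].
#' @export
remove_transients <- function(m) {
  comp <- strong_components(m)
  if (comp$no == 1) return(m)
  memb <- comp$membership[m$states]
  tr <- m$transitions[m$transitions$p > 0, , drop = FALSE]
  leaves <- unique(memb[tr$from][memb[tr$from] != memb[tr$to]])
  terminal <- setdiff(unique(memb), leaves)
  if (length(terminal) == 0)
    fc_inference_error("no terminal recurrent class found")
  if (length(terminal) > 1)
    fc_inference_error(sprintf(
      "machine is non-ergodic: %d terminal recurrent classes", length(terminal)))
  keep <- m$states[memb == terminal]
  tr <- tr[tr$from %in% keep & tr$to %in% keep, , drop = FALSE]
  for (s in unique(tr$from)) {
    sel <- tr$from == s
    tr$p[sel] <- tr$p[sel] / sum(tr$p[sel])
  }
  csm(tr, emissions = m$emissions,
      suffixes = if (is.null(m$suffixes)) NULL else m$suffixes[keep],
      states = keep, alphabet = m$alphabet)
}

#' Prune improbable transitions
#'
#' Occasional misassigned data points (tail events that land in the wrong
#' certain region) show up as extra transitions with very small
#' probability.  This removes every transition with probability below
#' `threshold`, renormalises, and re-restricts to the recurrent class.
#' The removed edges are recorded in the `"pruned"` attribute.
#'
#' @param m a [csm()].
#' @param threshold probability cutoff in `[0, 1)`; 0 disables pruning.
#' @return The pruned [csm()] with attribute `"pruned"` (data frame of
#'   removed edges, possibly empty).
#' @export
prune_transitions <- function(m, threshold) {
  if (threshold < 0 || threshold >= 1)
    fc_config_error("prune threshold must lie in [0, 1)")
  drop <- m$transitions$p < threshold & m$transitions$p > 0
  pruned <- m$transitions[drop, , drop = FALSE]
  if (!any(drop)) {
    attr(m, "pruned") <- pruned
    return(m)
  }
  tr <- m$transitions[!drop & m$transitions$p > 0, , drop = FALSE]
  if (!all(m$states %in% tr$from))
    fc_inference_error("pruning removed every transition of a state; lower the threshold")
  for (s in unique(tr$from)) {
    sel <- tr$from == s
    tr$p[sel] <- tr$p[sel] / sum(tr$p[sel])
  }
  out <- tryCatch(
    remove_transients(csm(tr, emissions = m$emissions, suffixes = m$suffixes,
                          states = m$states, alphabet = m$alphabet)),
    error = function(e)
      fc_inference_error(paste0("pruning disconnected the machine (",
                                conditionMessage(e), "); lower the threshold")))
  attr(out, "pruned") <- pruned
  out
}

#' Attach mixture emissions to a machine
#'
#' Binds mixture component `i` (in ascending order of mean) to symbol `i`,
#' so the machine can be evaluated as a generative model of the raw trace
#' (forward likelihood, Viterbi, model distance).  The certainty partition
#' plays no role here: it is an inference device only.
#'
#' @param m a [csm()] whose alphabet size equals the number of mixture
#'   components.
#' @param mixture a `gmix`.
#' @return The machine with `emissions` filled in.
#' @export
attach_emissions <- function(m, mixture) {
  comp <- mixture$components[order(mixture$components$mean), , drop = FALSE]
  if (nrow(comp) != length(m$alphabet))
    fc_config_error(sprintf("alphabet size %d != number of mixture components %d",
                            length(m$alphabet), nrow(comp)))
  m$emissions <- data.frame(symbol = m$alphabet, weight = comp$weight,
                            mean = comp$mean, sd = comp$sd)
  m
}

#' Audit state self-consistency
#'
#' After convergence, member histories of one causal state should have
#' pairwise equivalent next-symbol distributions at the reconstruction's
#' significance level.  This recomputes all within-state pairwise tests;
#' occasional rejections at rate `alpha` are expected by construction.
#'
#' @param states a `causal_states` object.
#' @param counts the matching `suffix_counts`.
#' @param alpha significance level.
#' @param method test passed to [test_equivalence()].
#' @return Data frame with columns `state`, `history_a`, `history_b`,
#'   `p_value`, `distinct`.
#' @export
audit_causal_states <- function(states, counts, alpha = 0.05,
                                method = c("chi2", "ks")) {
  method <- match.arg(method)
  rows <- list()
  for (i in seq_along(states$states)) {
    members <- states$states[[i]]
    members <- members[counts$totals[members] > 0]
    if (length(members) < 2) next
    for (a in seq_along(members)) for (b in seq_along(members)) {
      if (a >= b) next
      r <- test_equivalence(counts$counts[members[a], ],
                            counts$counts[members[b], ], alpha, method)
      rows[[length(rows) + 1L]] <- data.frame(
        state = i, history_a = members[a], history_b = members[b],
        p_value = r$p_value, distinct = r$distinct)
    }
  }
  if (!length(rows))
    return(data.frame(state = integer(), history_a = character(),
                      history_b = character(), p_value = numeric(),
                      distinct = logical()))
  do.call(rbind, rows)
}
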