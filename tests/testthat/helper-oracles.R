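# Independent brute-force oracles and small generators used across the
# suite.  Everything here enumerates exhaustively or simulates naively; the
# oracles share no code with the implementation paths they check.

# Exhaustive path-sum likelihood: enumerate every (state, transition)
# path, multiply stationary start weight, transition probabilities and
# Gaussian densities, and sum.
brute_forward <- function(m, x) {
  pi0 <- stationary_distribution(m)
  tr <- m$transitions[m$transitions$p > 0, , drop = FALSE]
  total <- 0
  rec <- function(s, t, p) {
    if (t > length(x)) {
      total <<- total + p
      return(invisible())
    }
    rows <- which(tr$from == s)
    for (i in rows) {
      em <- m$emissions[m$emissions$symbol == tr$symbol[i], ]
      rec(tr$to[i], t + 1, p * tr$p[i] * dnorm(x[t], em$mean, em$sd))
    }
  }
  for (s in m$states) rec(s, 1, pi0[[s]])
  log(total)
}

# Exhaustive most-probable-path search.  Exact ties (possible with
# rational transition probabilities) are resolved the way the dynamic
# programme promises: lowest state id, decided from the end of the path
# backwards (final state first, then its predecessor, and so on).
brute_viterbi <- function(m, x) {
  pi0 <- stationary_distribution(m)
  tr <- m$transitions[m$transitions$p > 0, , drop = FALSE]
  all_paths <- list()
  all_logp <- numeric(0)
  rec <- function(s, t, logp, path) {
    if (t > length(x)) {
      all_paths[[length(all_paths) + 1L]] <<- path
      all_logp[length(all_logp) + 1L] <<- logp
      return(invisible())
    }
    rows <- which(tr$from == s)
    for (i in rows) {
      em <- m$emissions[m$emissions$symbol == tr$symbol[i], ]
      rec(tr$to[i], t + 1,
          logp + log(tr$p[i]) + dnorm(x[t], em$mean, em$sd, log = TRUE),
          c(path, tr$to[i]))
    }
  }
  for (s in m$states) rec(s, 1, log(pi0[[s]]), character(0))
  top <- max(all_logp)
  tied <- all_paths[all_logp > top - 1e-9]
  if (length(tied) > 1) {
    key <- vapply(tied, function(p)
      paste(sprintf("%02d", rev(match(p, m$states))), collapse = ""),
      character(1))
    tied <- tied[order(key)]
  }
  list(logp = top, path = tied[[1]])
}

# Random strongly connected unifilar machine with Gaussian emissions.
random_machine <- function(n_states, k, seed) {
  set.seed(seed)
  for (attempt in 1:50) {
    rows <- list()
    for (s in seq_len(n_states)) {
      p <- as.numeric(rmultinom(1, 20, rep(1, k))) + 0.2
      p <- p / sum(p)
      to <- sample(n_states, k, replace = TRUE)
      for (a in seq_len(k))
        rows[[length(rows) + 1L]] <- data.frame(
          from = paste0("q", s), symbol = a - 1L, to = paste0("q", to[a]), p = p[a])
    }
    em <- data.frame(symbol = seq_len(k) - 1L,
                     mean = seq(0.2, 0.8, length.out = k),
                     sd = runif(k, 0.05, 0.15))
    m <- csm(do.call(rbind, rows), emissions = em)
    ok <- tryCatch({
      stationary_distribution(m)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(m)
  }
  stop("could not build a strongly connected random machine")
}

# "HLU" notation -> integer symbols with NA nulls (L=0, H=1, U=null).
str_to_syms <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- match(ch, c("L", "H")) - 1L
  out[ch == "U"] <- NA_integer_
  out
}

# Noiseless test processes -------------------------------------------------

# i.i.d. biased coin
iid_sequence <- function(n, p1 = 0.4, seed = 1) {
  set.seed(seed)
  sample(0:1, n, replace = TRUE, prob = c(1 - p1, p1))
}

# deterministic alternation 0101...
alternating_sequence <- function(n) rep_len(c(0L, 1L), n)

# golden-mean process: after a 1 always 0; after a 0 a fair coin
golden_mean_sequence <- function(n, seed = 1) {
  set.seed(seed)
  out <- integer(n)
  prev <- 0L
  for (i in seq_len(n)) {
    out[i] <- if (prev == 1L) 0L else sample(0:1, 1)
    prev <- out[i]
  }
  out
}

# Group histories of length <= L by their exact next-symbol morph under the
# true process (supplied as a function h -> probability vector, or NULL if
# the history cannot occur).  This is the exhaustive oracle for the number
# of causal states of a noiseless process.
oracle_state_count <- function(morph, k, L) {
  hists <- ""
  for (len in seq_len(L))
    hists <- c(hists, as.vector(outer(hists[nchar(hists) == len - 1],
                                      0:(k - 1), paste0)))
  morphs <- lapply(hists, morph)
  keep <- !vapply(morphs, is.null, logical(1))
  sig <- vapply(morphs[keep], function(p) paste(round(p, 12), collapse = ","),
                character(1))
  length(unique(sig))
}

# Canonical edge set of a machine, with states renamed by the symbol that
# enters them (valid when every state has a unique incoming symbol).
edge_set_by_entry_symbol <- function(m) {
  tr <- m$transitions[m$transitions$p > 0, , drop = FALSE]
  entry <- tapply(tr$symbol, tr$to, function(s) paste(sort(unique(s)), collapse = ""))
  if (anyDuplicated(unname(entry))) return(NULL)
  rename <- setNames(paste0("via", entry), names(entry))
  sort(paste(rename[tr$from], tr$symbol, rename[tr$to], sep = "->"))
}
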