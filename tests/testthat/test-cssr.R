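test_that("window counting discards null-touching windows whole", {
  cw <- count_windows(str_to_syms("HLHLU"), max_length = 1, k = 2)
  # length-2 windows: HL, LH, HL counted; LU discarded
  expect_equal(unname(cw$counts["1", ]), c(2, 0))
  expect_equal(unname(cw$counts["0", ]), c(0, 1))
  expect_equal(cw$n_windows, c(4L, 3L))
  expect_equal(cw$n_certain, 4L)

  expect_error(count_windows(rep(NA_integer_, 50), 1, k = 2),
               class = "fretcssr_data_error")
  expect_error(count_windows(c(0L, NA, 1L, NA, 0L), 1, k = 2),
               class = "fretcssr_data_error")  # no adjacent certain pair
})

test_that("window counts match a direct scan on random null-riddled sequences", {
  set.seed(10)
  for (rep in 1:5) {
    s <- sample(c(0:2, NA), 400, replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
    cw <- count_windows(s, max_length = 2, k = 3)
    # brute scan of all length-2 windows
    pairs <- cbind(s[-length(s)], s[-1])
    ok <- !is.na(pairs[, 1]) & !is.na(pairs[, 2])
    len1 <- rownames(cw$counts) %in% as.character(0:2)
    expect_equal(sum(cw$counts[len1, ]), sum(ok))
    for (h in 0:2) for (a in 0:2) {
      expected <- sum(ok & pairs[, 1] == h & pairs[, 2] == a)
      got <- if (as.character(h) %in% rownames(cw$counts))
        cw$counts[as.character(h), as.character(a)] else 0
      expect_equal(unname(got), expected)
    }
  }
})

test_that("suggested history length follows the expected-count floor", {
  expect_equal(suggest_max_length(60, 2), 1L)
  expect_equal(suggest_max_length(10000, 2), 8L)
  expect_equal(suggest_max_length(2000, 2), 6L)  # 2000/2^6 = 31.25 >= 25
  expect_gte(suggest_max_length(5, 3), 1L)
})

test_that("chi-squared equivalence behaves on hand-checked cases", {
  r <- test_equivalence(c(40, 60), c(40, 60))
  expect_equal(r$p_value, 1)
  expect_false(r$distinct)

  r2 <- test_equivalence(c(90, 10), c(10, 90), alpha = 0.05)
  # 4 cells of (|40| - 0.5)^2 / 50 with the 2x2 continuity correction
  expect_equal(r2$statistic, 4 * 39.5^2 / 50, tolerance = 1e-12)
  expect_true(r2$distinct)
  expect_lt(r2$p_value, 1e-25)
  expect_equal(r2$df, 1L)

  # sparse cells are merged, not dropped
  r3 <- test_equivalence(c(50, 50, 1), c(50, 50, 0), alpha = 0.05)
  expect_false(r3$distinct)
  expect_error(test_equivalence(c(0, 0), c(1, 1)), class = "fretcssr_config_error")
})

test_that("KS variant agrees on obvious cases", {
  expect_false(test_equivalence(c(50, 50), c(50, 50), method = "ks")$distinct)
  expect_true(test_equivalence(c(95, 5), c(5, 95), method = "ks")$distinct)
})

test_that("memoryless sequences collapse to a single state", {
  s <- iid_sequence(2000, p1 = 0.4, seed = 20)
  cw <- count_windows(s, 2, k = 2)
  st <- infer_causal_states(cw, cssr_config(max_length = 2))
  expect_equal(length(st$states), 1L)
  m <- remove_transients(determinize(st, cw))
  expect_equal(length(m$states), 1L)
})

test_that("deterministic alternation yields two one-edge states", {
  s <- alternating_sequence(400)
  cw <- count_windows(s, 2, k = 2)
  st <- infer_causal_states(cw, cssr_config(max_length = 2))
  m <- remove_transients(determinize(st, cw))
  expect_equal(length(m$states), 2L)
  tr <- m$transitions[m$transitions$p > 0, ]
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$p, c(1, 1))
  expect_equal(sort(tr$symbol), c(0L, 1L))
  expect_equal(length(m$states),
               oracle_state_count(function(h) {
                 last <- substr(h, nchar(h), nchar(h))
                 if (h == "") return(c(0.5, 0.5))
                 if (grepl("00|11", h)) return(NULL)
                 if (last == "0") c(0, 1) else c(1, 0)
               }, k = 2, L = 2) - 1L)
  # oracle counts the empty history's marginal as its own class; the
  # machine's recurrent part has exactly the two conditional classes
})

test_that("the golden-mean process is reconstructed with two states", {
  s <- golden_mean_sequence(5000, seed = 21)
  cw <- count_windows(s, 2, k = 2)
  st <- infer_causal_states(cw, cssr_config(max_length = 2))
  m <- remove_transients(determinize(st, cw))
  expect_equal(length(m$states), 2L)
  # oracle: histories group by exact future distribution into 2 classes
  oracle <- oracle_state_count(function(h) {
    if (grepl("11", h)) return(NULL)
    if (h == "") return(NULL)             # marginal, not a conditional class
    last <- substr(h, nchar(h), nchar(h))
    if (last == "1") c(1, 0) else c(0.5, 0.5)
  }, k = 2, L = 2)
  expect_equal(length(m$states), oracle)
  # after a 1, the next symbol is always 0
  one_state <- m$transitions$to[m$transitions$symbol == 1 & m$transitions$p > 0][1]
  out <- m$transitions[m$transitions$from == one_state & m$transitions$p > 0, ]
  expect_equal(out$symbol, 0L)
  expect_equal(out$p, 1)
})

test_that("chi-squared splitting holds its nominal type-I error rate", {
  set.seed(22)
  rejections <- 0L
  runs <- 1000L
  for (i in seq_len(runs)) {
    a <- rmultinom(1, 200, c(0.6, 0.3, 0.1))[, 1]
    b <- rmultinom(1, 200, c(0.6, 0.3, 0.1))[, 1]
    rejections <- rejections + test_equivalence(a, b, alpha = 0.05)$distinct
  }
  se <- sqrt(0.05 * 0.95 / runs)
  expect_lt(abs(rejections / runs - 0.05), 3 * se)
})

test_that("determinisation splits non-unifilar groupings and keeps unifilar ones", {
  s <- golden_mean_sequence(3000, seed = 23)
  cw <- count_windows(s, 2, k = 2)
  st <- infer_causal_states(cw, cssr_config(max_length = 2))
  m1 <- determinize(st, cw)
  m2 <- determinize(m1$suffixes, cw)
  expect_equal(m2$suffixes, m1$suffixes)
  expect_equal(m2$transitions$p, m1$transitions$p)

  # deliberately mis-group histories of a two-state process so that members
  # of one group disagree about the successor on symbol 0: the group must
  # split until every (state, symbol) has a unique successor
  sb <- simulate_trace(two_state_machine(), 2000, seed = 77)$symbols
  cwb <- count_windows(sb, 2, k = 2)
  bad_groups <- list(c(".", "0", "1"), c("00", "01", "10", "11"))
  mb <- determinize(bad_groups, cwb)
  key2 <- paste(mb$transitions$from, mb$transitions$symbol)
  expect_false(anyDuplicated(key2) > 0)
  expect_gte(length(mb$states), 3L)
  for (st2 in mb$states) {
    for (a in 0:1) {
      succ <- mb$transitions$to[mb$transitions$from == st2 &
                                mb$transitions$symbol == a]
      expect_lte(length(succ), 1L)
    }
  }
})

test_that("transient removal keeps exactly the terminal recurrent class", {
  m <- csm(data.frame(from = c("t1", "t2", "a", "b"),
                      symbol = c(0L, 0L, 0L, 1L),
                      to = c("t2", "a", "b", "a"),
                      p = 1), validate = TRUE)
  out <- remove_transients(m)
  expect_setequal(out$states, c("a", "b"))
  expect_equal(sum(out$transitions$p > 0), 2)

  sc <- two_state_machine()
  expect_identical(remove_transients(sc)$states, sc$states)

  # two terminal classes -> non-ergodic error
  m2 <- csm(data.frame(from = c("t", "t", "a", "b"),
                       symbol = c(0L, 1L, 0L, 1L),
                       to = c("a", "b", "a", "b"),
                       p = c(0.5, 0.5, 1, 1)))
  expect_error(remove_transients(m2), class = "fretcssr_inference_error")
})

test_that("pruning removes weak edges and renormalises", {
  m <- csm(data.frame(from = c("A", "A", "A", "B", "B"),
                      symbol = c(0L, 1L, 2L, 1L, 0L),
                      to = c("A", "B", "B", "B", "A"),
                      p = c(0.899, 0.1, 0.001, 0.9, 0.1)),
           emissions = data.frame(symbol = 0:2, mean = c(0.2, 0.5, 0.8), sd = 0.1))
  expect_identical(prune_transitions(m, 0)$transitions, m$transitions)

  pr <- prune_transitions(m, 0.01)
  expect_equal(nrow(attr(pr, "pruned")), 1L)
  expect_equal(attr(pr, "pruned")$p, 0.001)
  rows <- pr$transitions[pr$transitions$from == "A", ]
  expect_equal(sum(rows$p), 1, tolerance = 1e-12)
  expect_equal(sort(rows$p), sort(c(0.899, 0.1) / 0.999), tolerance = 1e-12)

  # pruning everything out of a state is an error
  expect_error(prune_transitions(m, 0.95), class = "fretcssr_inference_error")
})

test_that("emissions bind components to symbols in ascending mean order", {
  m <- two_state_machine()
  m$emissions <- NULL
  g <- fretcssr:::new_gmix(data.frame(weight = c(0.4, 0.6),
                                      mean = c(0.72, 0.28), sd = c(0.11, 0.09)),
                           0, 2, 100)
  out <- attach_emissions(m, g)
  expect_equal(out$emissions$mean, c(0.28, 0.72))
  expect_equal(out$emissions$symbol, 0:1)
  g1 <- fretcssr:::new_gmix(data.frame(weight = 1, mean = 0.5, sd = 0.1), 0, 1, 100)
  expect_error(attach_emissions(m, g1), class = "fretcssr_config_error")
})

test_that("fully certain sequences give the same machine as plain discrete input", {
  sim <- simulate_trace(two_state_machine(), 3000, seed = 26)
  s <- sim$symbols  # noiseless symbol path, no nulls
  cw <- count_windows(s, 2, k = 2)
  st <- infer_causal_states(cw, cssr_config(max_length = 2))
  m <- remove_transients(determinize(st, cw))
  expect_equal(length(m$states), 2L)
  # and inserting nulls only rescales counts, not the architecture
  s2 <- s
  set.seed(24)
  s2[sample(length(s2), 300)] <- NA
  cw2 <- count_windows(s2, 2, k = 2)
  m2 <- remove_transients(determinize(infer_causal_states(cw2,
        cssr_config(max_length = 2)), cw2))
  expect_equal(length(m2$states), 2L)
})

test_that("state members pass the self-consistency audit on clean processes", {
  s <- golden_mean_sequence(5000, seed = 25)
  cw <- count_windows(s, 2, k = 2)
  st <- infer_causal_states(cw, cssr_config(max_length = 2))
  audit <- audit_causal_states(st, cw, alpha = 0.05)
  expect_true(all(!audit$distinct))
})
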