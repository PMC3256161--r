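#' Fit a K-component Gaussian mixture to signal levels
#'
#' Maximum-likelihood fit of a univariate Gaussian mixture with unequal
#' variances, the model family appropriate for FRET-efficiency histograms
#' where each molecular level contributes a roughly Gaussian peak.  `K = 1`
#' uses the closed-form MLE.  `K >= 2` runs expectation--maximisation from
#' several starting points -- quantile blocks of the sorted data, evenly
#' spaced means, a seeded k-means partition, and random restarts -- and
#' keeps the best log-likelihood; level occupancies in kinetic data can be
#' very unbalanced (a rarely visited level holding a few percent of the
#' mass), and single-start EM routinely merges such peaks.  Components are
#' returned in ascending order of mean, which also fixes the symbol
#' indexing used downstream (symbol `i` is component `i`).
#'
#' @param values numeric signal levels (at least `3 * k` points).
#' @param k number of components (>= 1).
#' @param seed integer seed controlling k-means and the random restarts;
#'   the fit is deterministic given the seed.
#' @param restarts number of random restarts added to the three
#'   deterministic initialisations (default 5).
#' @return An object of class `gmix`: list with `components` (data frame
#'   `weight`, `mean`, `sd`, ascending mean), `loglik` (nats), `n_params`
#'   (`3K - 1`), `aic`, `bic` and `n`.
#' @export
fit_mixture <- function(values, k, seed = 1L, restarts = 5L) {
  values <- as.numeric(values)
  k <- as.integer(k)
  if (k < 1) fc_config_error("k must be >= 1")
  if (length(values) < 3 * k)
    fc_data_error(sprintf("need at least %d points to fit %d components", 3 * k, k))
  if (k == 1) {
    mu <- mean(values)
    s <- sqrt(mean((values - mu)^2))
    if (s < 1e-4) fc_data_error("degenerate fit: component sd collapsed below 1e-4")
    ll <- sum(stats::dnorm(values, mu, s, log = TRUE))
    return(new_gmix(data.frame(weight = 1, mean = mu, sd = s), ll, k, length(values)))
  }
  set.seed(seed)
  # The unequal-variance Gaussian mixture likelihood is unbounded: a
  # component shrinking onto a handful of coincidentally close points
  # gains unlimited density.  Such spikes are numerical artifacts, not
  # signal levels, so any component narrower than 2% of the overall data
  # spread is rejected as degenerate.
  sd_floor <- max(1e-4, 0.02 * stats::sd(values))
  # short EM runs from every start, then polish the best to convergence
  fits <- list()
  for (mu0 in mixture_starts(values, k, restarts)) {
    fit <- em_gaussian_mixture(values, k, mu0, tol = 1e-6, maxit = 50L,
                               sd_floor = sd_floor)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  fits <- fits[order(vapply(fits, `[[`, numeric(1), "loglik"),
                     decreasing = TRUE)]
  best <- NULL
  for (fit in fits) {
    polished <- em_gaussian_mixture(values, k, fit$mu, w = fit$w, sd = fit$sd,
                                    sd_floor = sd_floor)
    if (!is.null(polished)) {
      best <- polished
      break
    }
  }
  if (is.null(best))
    fc_data_error(sprintf(
      "mixture fit with %d components failed: all starts degenerate", k))
  comp <- data.frame(weight = best$w, mean = best$mu, sd = best$sd)
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  new_gmix(comp, best$loglik, k, length(values))
}

# Candidate mean vectors for EM initialisation.
mixture_starts <- function(x, k, restarts) {
  starts <- list(
    # medians of k equal-count blocks of the sorted data
    as.numeric(stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k))),
    # evenly spaced across the observed range
    seq(min(x), max(x), length.out = k + 2L)[2:(k + 1L)]
  )
  km <- tryCatch(stats::kmeans(x, centers = k, nstart = 10L),
                 error = function(e) NULL)
  if (!is.null(km)) starts <- c(starts, list(sort(as.numeric(km$centers))))
  c(starts, lapply(seq_len(restarts), function(i) sample(x, k)))
}

# Univariate EM for a k-component Gaussian mixture from given start means.
# Returns NULL when a component collapses (weight or sd degenerate).
em_gaussian_mixture <- function(x, k, mu, w = NULL, sd = NULL,
                                tol = 1e-8, maxit = 1000L,
                                sd_floor = 1e-4) {
  n <- length(x)
  if (is.null(w)) w <- rep(1 / k, k)
  if (is.null(sd)) sd <- rep(max(stats::sd(x) / k, sd_floor), k)
  ll_old <- -Inf
  ll <- -Inf
  for (it in seq_len(maxit)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    tot <- rowSums(dens)
    if (any(tot <= 0)) return(NULL)
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 2)) return(NULL)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd <- sqrt(vapply(seq_len(k),
                      function(j) sum(r[, j] * (x - mu[j])^2) / nk[j],
                      numeric(1)))
    if (any(!is.finite(sd))) return(NULL)
    sd <- pmax(sd, sd_floor)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  if (any(sd <= sd_floor)) return(NULL)
  list(w = w, mu = mu, sd = sd, loglik = ll)
}

new_gmix <- function(components, loglik, k, n) {
  n_params <- 3L * k - 1L
  structure(list(components = components, loglik = loglik,
                 n_params = n_params,
                 aic = 2 * n_params - 2 * loglik,
                 bic = log(n) * n_params - 2 * loglik,
                 n = n),
            class = "gmix")
}

#' @export
print.gmix <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, loglik = %.4g, AIC = %.4g\n",
              nrow(x$components), x$loglik, x$aic))
  print(x$components, digits = 4)
  invisible(x)
}

#' Select the number of mixture components by information criterion
#'
#' Fits mixtures with `k = 1..k_max` components and keeps the fit with
#' minimal AIC (default) or BIC; ties go to the smaller `k`.  A component
#' count that fails to fit is skipped with a warning.  A fixed `k_fixed`
#' bypasses selection entirely -- useful when a drifting spectrum inflates
#' the apparent number of peaks but the level count is known.
#'
#' @param values numeric signal levels.
#' @param k_max largest component count to try (>= 1).
#' @param seed integer seed passed to [fit_mixture()].
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param k_fixed optional fixed component count overriding selection.
#' @return The selected `gmix`, with attribute `"candidates"`: a data frame
#'   of `k`, `loglik`, `aic`, `bic` for every attempted fit.
#' @export
select_mixture <- function(values, k_max = 4L, seed = 1L,
                           criterion = c("aic", "bic"), k_fixed = NULL) {
  criterion <- match.arg(criterion)
  if (!is.null(k_fixed)) return(fit_mixture(values, k_fixed, seed))
  if (k_max < 1) fc_config_error("k_max must be >= 1")
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- tryCatch(fit_mixture(values, k, seed), error = function(e) {
      warning(sprintf("skipping k = %d: %s", k, conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) fc_data_error("no mixture model could be fitted")
  cand <- data.frame(k = which(ok),
                     loglik = vapply(fits[ok], `[[`, numeric(1), "loglik"),
                     aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
                     bic = vapply(fits[ok], `[[`, numeric(1), "bic"))
  score <- if (criterion == "aic") cand$aic else cand$bic
  best <- fits[[cand$k[which.min(score)]]]
  attr(best, "candidates") <- cand
  best
}
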