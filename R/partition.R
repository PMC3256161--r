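#' Build a certainty partition from a fitted mixture
#'
#' Places two boundaries per mixture component at its `q` and `1 - q`
#' normal quantiles (default: the permille quantiles).  The regions cut out
#' by the sorted boundaries are labelled with a component index where they
#' lie inside exactly one component's quantile interval ("certain"
#' assignment) and with the null label everywhere else -- both in overlap
#' regions between components and in the unbounded extreme tails, where a
#' point cannot be attributed to a single component with confidence.
#'
#' Partitioning fails (with an error naming the components) when one
#' component's quantile interval nests inside another's, which can only
#' happen for levels extremely close together or with very different
#' variances.
#'
#' @param mixture a `gmix` from [fit_mixture()]/[select_mixture()].
#' @param q tail quantile defining "certain" mass, `0 < q < 0.5`
#'   (default `0.001`).
#' @return An object of class `fret_partition`: list with `boundaries`
#'   (sorted, length `2K`), `region_labels` (length `2K + 1`; component
#'   index `0..K-1` or `NA` for null), `kept_fraction` (per-component mass
#'   in its certain region) and `q`.
#' @export
build_partition <- function(mixture, q = 0.001) {
  if (!inherits(mixture, "gmix")) fc_config_error("mixture must be a gmix object")
  if (!(q > 0 && q < 0.5)) fc_config_error("q must lie in (0, 0.5)")
  comp <- mixture$components
  K <- nrow(comp)
  lo <- stats::qnorm(q, comp$mean, comp$sd)
  hi <- stats::qnorm(1 - q, comp$mean, comp$sd)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i != j && lo[j] < lo[i] && hi[i] < hi[j])
      fc_partition_error(sprintf(
        "appropriate partitions cannot be found: component %d nests inside component %d",
        i - 1L, j - 1L))
  }
  boundaries <- sort(c(lo, hi))
  if (any(diff(boundaries) <= 0))
    fc_partition_error("coincident partition boundaries; components indistinguishable")
  part <- new_partition(boundaries, region_labels_for(boundaries, lo, hi), q)
  part$kept_fraction <- kept_fractions(part, mixture)
  if (any(part$kept_fraction <= 0))
    fc_partition_error(sprintf(
      "component(s) %s have no certain region (fully overlapped)",
      paste(which(part$kept_fraction <= 0) - 1L, collapse = ", ")))
  part
}

new_partition <- function(boundaries, region_labels, q) {
  structure(list(boundaries = boundaries, region_labels = region_labels,
                 kept_fraction = NULL, q = q),
            class = "fret_partition")
}

# Label each of the 2K+1 regions: component index (0-based) if the region
# lies inside exactly one component's quantile interval, NA otherwise.
region_labels_for <- function(boundaries, lo, hi) {
  edges <- c(-Inf, boundaries, Inf)
  labels <- rep(NA_integer_, length(boundaries) + 1)
  for (r in seq_along(labels)) {
    l <- edges[r]; u <- edges[r + 1]
    if (!is.finite(l) || !is.finite(u)) next
    mid <- (l + u) / 2
    inside <- which(mid > lo & mid < hi)
    if (length(inside) == 1) labels[r] <- inside - 1L
  }
  labels
}

# Per-component probability mass inside that component's certain region(s).
kept_fractions <- function(part, mixture) {
  comp <- mixture$components
  edges <- c(-Inf, part$boundaries, Inf)
  vapply(seq_len(nrow(comp)), function(i) {
    rs <- which(part$region_labels == i - 1L)
    sum(vapply(rs, function(r) {
      stats::pnorm(edges[r + 1], comp$mean[i], comp$sd[i]) -
        stats::pnorm(edges[r], comp$mean[i], comp$sd[i])
    }, numeric(1)))
  }, numeric(1))
}

#' @export
print.fret_partition <- function(x, ...) {
  cat(sprintf("Partition: %d boundaries, q = %g\n", length(x$boundaries), x$q))
  edges <- c(-Inf, x$boundaries, Inf)
  for (r in seq_along(x$region_labels)) {
    lab <- if (is.na(x$region_labels[r])) "null" else sprintf("symbol %d", x$region_labels[r])
    cat(sprintf("  (%.4g, %.4g] -> %s\n", edges[r], edges[r + 1], lab))
  }
  if (!is.null(x$kept_fraction))
    cat("  kept fractions:", paste(sprintf("%.4f", x$kept_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Equalise per-component kept mass across the partition
#'
#' The partition discards a fraction of each component's mass into the null
#' label.  If that fraction differs between components, the relative
#' frequencies of the surviving symbols are skewed and the transition
#' probabilities of the reconstructed machine inherit the bias.  This step
#' finds the minimum kept fraction and shrinks every other component's
#' certain region towards its mean until all kept fractions are equal to
#' that minimum, leaving the symbol retention unbiased.
#'
#' The excess mass each component must additionally discard is split
#' between its two certain-region edges in proportion to the mass already
#' excluded on each side, and the new edges are found on the component's
#' own normal quantile function (exact, no iteration).
#'
#' @param partition a [build_partition()] result.
#' @param mixture the `gmix` the partition was built from.
#' @return The adjusted `fret_partition`; all `kept_fraction` values equal
#'   to the pre-adjustment minimum (within `1e-10`).
#' @export
equalize_partition <- function(partition, mixture) {
  comp <- mixture$components
  kept <- kept_fractions(partition, mixture)
  m <- min(kept)
  b <- partition$boundaries
  edges <- c(-Inf, b, Inf)
  for (i in seq_len(nrow(comp))) {
    if (kept[i] <= m + 1e-12) next
    rs <- which(partition$region_labels == i - 1L)
    if (length(rs) != 1)
      fc_partition_error(sprintf("component %d has %d certain regions; cannot equalise",
                                 i - 1L, length(rs)))
    r <- rs
    a_ <- edges[r]; b_ <- edges[r + 1]
    Fa <- stats::pnorm(a_, comp$mean[i], comp$sd[i])
    Fb <- stats::pnorm(b_, comp$mean[i], comp$sd[i])
    excess <- (Fb - Fa) - m
    out <- Fa + (1 - Fb)
    eL <- excess * Fa / out
    eR <- excess - eL
    new_a <- stats::qnorm(Fa + eL, comp$mean[i], comp$sd[i])
    new_b <- stats::qnorm(Fb - eR, comp$mean[i], comp$sd[i])
    # region edges are boundaries r-1 and r of the sorted boundary vector
    b[r - 1] <- new_a
    b[r] <- new_b
    edges <- c(-Inf, b, Inf)
  }
  if (any(diff(b) <= 0))
    fc_partition_error("equalisation produced unsorted boundaries")
  out <- new_partition(b, partition$region_labels, partition$q)
  out$kept_fraction <- kept_fractions(out, mixture)
  if (max(out$kept_fraction) - min(out$kept_fraction) > 1e-10)
    fc_partition_error("equalisation failed to reach equal kept fractions")
  out
}

#' Symbolise a trace through a partition
#'
#' Maps every sample to the label of the region it falls in: a certain
#' symbol `0..K-1` where the point is attributable to a single mixture
#' component, the null symbol (`NA`) in overlap regions and extreme tails.
#' Values landing exactly on a boundary (a measure-zero event) are
#' conservatively assigned the null symbol.
#'
#' @param trace a [fret_trace()] or numeric vector.
#' @param partition a `fret_partition`.
#' @return An object of class `symbol_sequence`: list with `symbols`
#'   (integer vector, `NA` = null), `k` (alphabet size), `dt` and
#'   `source_length`.
#' @export
symbolize <- function(trace, partition) {
  trace <- as_trace(trace)
  v <- trace$values
  idx <- findInterval(v, partition$boundaries)
  sym <- partition$region_labels[idx + 1L]
  sym[v %in% partition$boundaries] <- NA_integer_
  k <- length(partition$boundaries) / 2L
  structure(list(symbols = as.integer(sym), k = as.integer(k),
                 dt = trace$dt, source_length = length(v)),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  n <- length(x$symbols)
  cat(sprintf("Symbol sequence: %d bins, alphabet size %d, %.1f%% null\n",
              n, x$k, 100 * mean(is.na(x$symbols))))
  cat(" ", substr(symbols_to_string(x), 1, 60),
      if (n > 60) "...\n" else "\n")
  invisible(x)
}

#' Render a symbol sequence as a single-character string
#'
#' Certain symbols become digits, the null symbol becomes `"U"`.
#'
#' @param symbols a `symbol_sequence` (or integer vector with `NA` nulls).
#' @return A character scalar.
#' @export
symbols_to_string <- function(symbols) {
  s <- if (inherits(symbols, "symbol_sequence")) symbols$symbols else symbols
  paste(ifelse(is.na(s), "U", as.character(s)), collapse = "")
}
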