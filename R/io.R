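#' Read a trace from delimited text
#'
#' Accepts one-column files (one value per line) or two-column files
#' (time, value), whitespace- or comma-delimited, with `#` comment lines
#' ignored.  For two-column input the sampling interval is inferred from
#' the time column and checked for uniformity (more than 1% step jitter is
#' an error); for one-column input `dt` must be supplied.
#'
#' @param path path to a readable text file.
#' @param dt sampling interval in seconds; required for one-column files,
#'   optional (overrides inference) for two-column files.
#' @return A [fret_trace()].
#' @export
read_trace <- function(path, dt = NULL) {
  if (!file.exists(path)) fc_data_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) fc_data_error(sprintf("%s: no data rows", path))
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || !ncol %in% 1:2)
    fc_data_error(sprintf("%s: expected 1 or 2 columns on every row", path))
  num <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(num, anyNA, logical(1)))
  if (length(bad))
    fc_data_error(sprintf("%s: non-numeric value on line %d", path, lineno[bad[1]]))
  mat <- do.call(rbind, num)
  if (ncol == 1) {
    if (is.null(dt)) fc_config_error("dt is required for one-column trace files")
    return(fret_trace(mat[, 1], dt))
  }
  times <- mat[, 1]
  steps <- diff(times)
  if (length(steps) < 1) {
    if (is.null(dt)) fc_config_error("cannot infer dt from a single row")
    return(fret_trace(mat[, 2], dt))
  }
  med <- stats::median(steps)
  if (med <= 0 || any(abs(steps - med) > 0.01 * med))
    fc_data_error(sprintf("%s: non-uniform time steps (jitter > 1%%)", path))
  fret_trace(mat[, 2], if (is.null(dt)) med else dt)
}

#' Write a trace as two-column text
#'
#' @param trace a [fret_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  t <- (seq_along(trace$values) - 1) * trace$dt
  writeLines(c("# time\tvalue",
               sprintf("%.10g\t%.10g", t, trace$values)), path)
  invisible(path)
}

machine_to_list <- function(m) {
  list(states = m$states,
       alphabet = m$alphabet,
       suffixes = if (is.null(m$suffixes)) NULL else
         lapply(m$suffixes, as.character),
       transitions = m$transitions[, c("from", "symbol", "to", "p", "count")],
       emissions = m$emissions)
}

#' Write a machine to JSON or GraphViz DOT
#'
#' JSON serialisation round-trips losslessly through [read_machine()].
#' DOT output draws one node per state and one edge per transition,
#' labelled `symbol : probability` (3 decimals), for rendering state
#' diagrams of the inferred kinetic scheme.
#'
#' @param m a [csm()].
#' @param path output path.
#' @param format `"json"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_machine <- function(m, path, format = c("json", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(machine_to_list(m), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    writeLines(machine_to_dot(m), path)
  }
  invisible(path)
}

#' Read a machine from its JSON serialisation
#'
#' @param path path written by [write_machine()] with `format = "json"`.
#' @return A [csm()].
#' @export
read_machine <- function(path) {
  if (!file.exists(path)) fc_data_error(sprintf("no such file: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$transitions)) fc_data_error(sprintf("%s: not a machine file", path))
  suffixes <- if (is.null(x$suffixes)) NULL else lapply(x$suffixes, as.character)
  csm(x$transitions,
      emissions = x$emissions,
      suffixes = suffixes,
      states = as.character(x$states),
      alphabet = x$alphabet)
}

#' GraphViz DOT source for a machine diagram
#'
#' @param m a [csm()].
#' @return Character vector of DOT lines.
#' @export
machine_to_dot <- function(m) {
  lines <- c("digraph machine {", "  rankdir=LR;", "  node [shape=circle];")
  for (s in m$states) {
    lab <- s
    if (!is.null(m$emissions)) {
      # annotate with the level(s) emitted on the state's incoming symbols
      inc <- unique(m$transitions$symbol[m$transitions$to == s & m$transitions$p > 0])
      mu <- m$emissions$mean[match(inc, m$emissions$symbol)]
      if (length(mu) && !anyNA(mu))
        lab <- sprintf("%s\\n%s", s, paste(sprintf("%.2f", mu), collapse = "/"))
    }
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];", s, lab))
  }
  tr <- m$transitions[m$transitions$p > 0, , drop = FALSE]
  tr <- tr[order(tr$from, tr$symbol), ]
  for (i in seq_len(nrow(tr)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%d : %.3f\"];",
                              tr$from[i], tr$to[i], tr$symbol[i], tr$p[i]))
  c(lines, "}")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   [pipeline_config()].
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) fc_data_error(sprintf("no such file: %s", path))
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}
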