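# Plain-text interchange formats: graphs with per-edge lags, and spike
# trains.  Both are TSV with a header line; `#` starts a comment.  Vertex
# indices are 1-based.

#' Write / read a graph with per-edge lags
#'
#' TSV with columns `src`, `dst`, `lag` (one edge per line, 1-based vertex
#' indices, lags in dimensionless time units).
#'
#' @param g An `scg_graph`.
#' @param lags Numeric per-edge lag vector aligned with `g$edges`.
#' @param path File path.
#' @return `write_graph_tsv` returns `path` invisibly; `read_graph_tsv`
#'   returns a list with elements `graph` (an `scg_graph`) and `lags`.
#' @export
write_graph_tsv <- function(g, lags, path) {
  stopifnot(inherits(g, "scg_graph"), length(lags) == nrow(g$edges))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n: %d", g$n), con)
  df <- data.frame(src = g$edges[, 1L], dst = g$edges[, 2L],
                   lag = as.double(lags))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  header <- grep("^# n:", readLines(path, n = 5L), value = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  stopifnot(all(c("src", "dst", "lag") %in% names(df)))
  n <- if (length(header)) as.integer(sub("^# n:\\s*", "", header[1L])) else
    max(df$src, df$dst)
  g <- scg_graph(n, cbind(df$src, df$dst))
  lags <- as.double(df$lag)
  attr(lags, "bounds") <- range(lags)
  list(graph = g, lags = lags)
}

#' Write / read a spike train
#'
#' TSV with columns `time`, `vertex`, rows sorted by time; the terminal
#' status is kept in a trailing comment line `# status: ...`.
#'
#' @param h A `spike_history`.
#' @param path File path.
#' @return `write_spikes_tsv` returns `path` invisibly; `read_spikes_tsv`
#'   returns a `spike_history`.
#' @export
write_spikes_tsv <- function(h, path) {
  stopifnot(inherits(h, "spike_history"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n: %d", h$n), con)
  write.table(as.data.frame(h), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sprintf("# status: %s", h$status), con)
  invisible(path)
}

#' @rdname write_spikes_tsv
#' @export
read_spikes_tsv <- function(path) {
  lines <- readLines(path)
  n_line <- grep("^# n:", lines, value = TRUE)
  status_line <- grep("^# status:", lines, value = TRUE)
  status <- if (length(status_line))
    sub("^# status:\\s*", "", status_line[1L]) else "reached_cap"
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t")
  stopifnot(all(c("time", "vertex") %in% names(df)))
  n <- if (length(n_line)) as.integer(sub("^# n:\\s*", "", n_line[1L])) else
    max(df$vertex)
  spike_history(df$time, df$vertex, n, status = status)
}
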