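#' Spike history container
#'
#' Holds the outcome of a simulation (or an externally observed spike
#' train): global spike times, the vertex that fired at each time, and how
#' the run terminated.  Times are non-decreasing in recording order and,
#' per vertex, strictly increasing with consecutive gaps of at least the
#' refractory period `delta`.
#'
#' @param time Numeric vector of spike times.
#' @param vertex Integer vector of firing vertices (1-based), same length.
#' @param n Vertex count of the underlying graph.
#' @param delta Refractory period the history was generated under (may be
#'   `NA` for externally supplied trains).
#' @param status One of `"died_out"`, `"reached_cap"`, `"reached_horizon"`.
#' @return An object of class `spike_history`.
#' @export
spike_history <- function(time, vertex, n, delta = NA_real_,
                          status = c("reached_cap", "died_out",
                                     "reached_horizon")) {
  status <- match.arg(status)
  stopifnot(length(time) == length(vertex))
  if (is.unsorted(time)) stop("spike times must be non-decreasing",
                              call. = FALSE)
  structure(list(time = as.double(time), vertex = as.integer(vertex),
                 n = as.integer(n), delta = delta, status = status),
            class = "spike_history")
}

#' @export
print.spike_history <- function(x, ...) {
  cat(sprintf("<spike_history> %d spikes on %d vertices, status: %s\n",
              length(x$time), x$n, x$status))
  invisible(x)
}

#' @export
as.data.frame.spike_history <- function(x, ...) {
  data.frame(time = x$time, vertex = x$vertex)
}

#' Spike times of one vertex
#'
#' @param h A `spike_history`.
#' @param vertex Vertex index.
#' @return Numeric vector of that vertex's firing times (strictly
#'   increasing).
#' @export
spike_times <- function(h, vertex) {
  stopifnot(inherits(h, "spike_history"))
  h$time[h$vertex == vertex]
}

check_sim_inputs <- function(g, lags, delta, vertex) {
  stopifnot(inherits(g, "scg_graph"))
  if (length(lags) != nrow(g$edges)) {
    stop("`lags` must supply exactly one delay per edge", call. = FALSE)
  }
  if (any(lags <= 0)) stop("all transmission lags must be positive",
                           call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (vertex < 1 || vertex > g$n) stop("vertex index out of range",
                                       call. = FALSE)
}

#' Free-running spike simulation
#'
#' Event-driven simulation of the excitable-refractory-delay dynamic: a
#' single kick spike is injected at `t = 0` at `kick`; every spike sends one
#' delayed arrival along each out-edge; an arrival makes its target fire
#' unless the target is refractory (within `delta` after its own last
#' spike), in which case the arrival is discarded.  The refractory window is
#' half-open, so an arrival at exactly `last spike + delta` fires; `delta`
#' is thus the attainable minimum inter-spike interval.
#'
#' The run stops when `max_spikes` spikes have been recorded
#' (`"reached_cap"`), when the next event lies beyond `t_max`
#' (`"reached_horizon"`), or when no pending arrivals remain
#' (`"died_out"`).
#'
#' @param g An `scg_graph` (strong connectivity recommended for sustained
#'   activity, not enforced).
#' @param lags Numeric vector of positive per-edge delays aligned with
#'   `g$edges` (see [assign_lags()]).
#' @param delta Refractory period, same time units as the lags.
#' @param kick Vertex receiving the kick-start spike.
#' @param max_spikes Cap on recorded spikes.
#' @param t_max Optional time horizon.
#' @return A [spike_history()].
#' @examples
#' g <- scg_graph(3, rbind(c(1, 2), c(2, 3), c(3, 1)))
#' h <- run_free(g, lags = c(50, 60, 70), delta = 20, max_spikes = 30)
#' interspike_intervals(h, 1)
#' @export
run_free <- function(g, lags, delta, kick = 1L, max_spikes = 100000L,
                     t_max = Inf) {
  check_sim_inputs(g, lags, delta, kick)
  res <- sim_core_cpp(g$n, g$edges - 1L, as.double(lags), delta,
                      as.integer(kick) - 1L, 0, as.integer(max_spikes),
                      t_max)
  spike_history(res$time, res$vertex + 1L, g$n, delta, res$status)
}

#' Periodically forced spike simulation
#'
#' As [run_free()], but stimulation pulses arrive at `force_vertex` at
#' times `0, p, 2p, ...`; the `t = 0` pulse plays the role of the kick.
#' Forced pulses obey the same refractory suppression: a pulse landing in a
#' refractory window has no effect.  While forcing continues the event
#' queue never empties, so the run ends at `max_spikes` or `t_max`.
#'
#' @inheritParams run_free
#' @param p Forcing period, `p > 0`.
#' @param force_vertex Vertex receiving the periodic pulses.
#' @return A [spike_history()].
#' @export
run_forced <- function(g, lags, delta, p, force_vertex = 1L,
                       max_spikes = 100000L, t_max = Inf) {
  check_sim_inputs(g, lags, delta, force_vertex)
  if (p <= 0) stop("forcing period `p` must be positive", call. = FALSE)
  res <- sim_core_cpp(g$n, g$edges - 1L, as.double(lags), delta,
                      as.integer(force_vertex) - 1L, p,
                      as.integer(max_spikes), t_max)
  spike_history(res$time, res$vertex + 1L, g$n, delta, res$status)
}

#' Inter-spike intervals at one vertex
#'
#' Drops the first `floor(burn_in * count)` spikes of the vertex (transient
#' before the dynamic settles near its attractor) and returns consecutive
#' differences of the remaining firing times.  Every interval is at least
#' the refractory period of the generating run.
#'
#' @param h A `spike_history`.
#' @param vertex Vertex index.
#' @param burn_in Fraction of that vertex's spikes to discard, in `[0, 1)`.
#' @return Numeric vector of intervals (length `>= 1`).
#' @export
interspike_intervals <- function(h, vertex, burn_in = 0) {
  stopifnot(inherits(h, "spike_history"), burn_in >= 0, burn_in < 1)
  tt <- spike_times(h, vertex)
  drop <- floor(burn_in * length(tt))
  tt <- tt[seq_along(tt) > drop]
  if (length(tt) < 2L) {
    stop("fewer than 2 spikes survive the burn-in at this vertex",
         call. = FALSE)
  }
  diff(tt)
}

#' Mean inter-spike interval per vertex
#'
#' @inheritParams interspike_intervals
#' @return Numeric vector of length `n`: the arithmetic mean inter-spike
#'   interval of each vertex after burn-in.
#' @export
mean_isi <- function(h, burn_in = 0) {
  stopifnot(inherits(h, "spike_history"))
  vapply(seq_len(h$n), function(v) {
    mean(interspike_intervals(h, v, burn_in))
  }, numeric(1))
}
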