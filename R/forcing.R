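# Entrainment under periodic forcing.
#
# A forced run is K:1 entrained when its long-run response is periodic with
# period K*p (K pulses per response cycle).  The detector operationalises
# "settles to a period of length Kp" directly: in the tail of the run,
# every probe spike at time t must be matched by a spike within `tol` of
# t + K*p (whenever t + K*p lies inside the observed range).  K is searched
# in ascending order, so the reported K is minimal.

#' Classify K:1 entrainment of a forced spike history
#'
#' Tests, for `K = 1, ..., k_max` in ascending order, whether the tail of
#' the probe vertex's spike train is invariant under a time shift of
#' `K * p` to within `tol`: each tail spike `t` with `t + K*p` inside the
#' observed range must have a matching spike within `tol` of `t + K*p`.
#' The first `K` that passes is reported (so `K` is minimal); if none
#' passes the history is `not_entrained`.
#'
#' @param h A `spike_history` from [run_forced()] (or any spike train).
#' @param p Forcing period used to generate `h`.
#' @param probe_vertex Vertex whose train is classified.
#' @param k_max Largest response/forcing ratio considered, default 8.
#' @param tol Time tolerance for a phase match, default 1 time unit.
#' @param tail_fraction Fraction of the probe's spikes (the last ones) used
#'   as the settled tail, default 0.25.
#' @return List of class `entrainment_result` with `status`
#'   (`"entrained"`/`"not_entrained"`), `K` (`NA` when not entrained), and
#'   `phase_spread` (largest matching deviation when entrained).
#' @examples
#' h <- spike_history(seq(0, 2000, by = 100), rep(1L, 21), n = 1,
#'                    status = "reached_cap")
#' classify_entrainment(h, p = 100)
#' @export
classify_entrainment <- function(h, p, probe_vertex = 1L, k_max = 8L,
                                 tol = 1.0, tail_fraction = 0.25) {
  stopifnot(inherits(h, "spike_history"), p > 0, k_max >= 1,
            tol >= 0, tail_fraction > 0, tail_fraction < 1)
  tt <- spike_times(h, probe_vertex)
  n_sp <- length(tt)
  tail_start <- floor((1 - tail_fraction) * n_sp) + 1L
  tail <- tt[tail_start:n_sp]
  if (length(tail) < 2L * k_max) {
    stop("too few tail spikes at the probe vertex to classify entrainment",
         call. = FALSE)
  }
  t_end <- tt[n_sp]
  for (K in seq_len(k_max)) {
    P <- K * p
    cand <- tail[tail + P <= t_end + tol]
    if (length(cand) < 2L) next
    target <- cand + P
    # distance from each target to its nearest spike
    pos <- findInterval(target, tt)
    lo <- ifelse(pos >= 1L, target - tt[pmax(pos, 1L)], Inf)
    hi <- ifelse(pos < n_sp, tt[pmin(pos + 1L, n_sp)] - target, Inf)
    miss <- pmin(lo, hi)
    if (all(miss <= tol)) {
      return(structure(list(status = "entrained", K = K,
                            phase_spread = max(miss)),
                       class = "entrainment_result"))
    }
  }
  structure(list(status = "not_entrained", K = NA_integer_,
                 phase_spread = NA_real_),
            class = "entrainment_result")
}

#' @export
print.entrainment_result <- function(x, ...) {
  if (x$status == "entrained") {
    cat(sprintf("<entrainment> %d:1 (phase spread %.3g)\n",
                x$K, x$phase_spread))
  } else {
    cat("<entrainment> not entrained\n")
  }
  invisible(x)
}

#' Scan a grid of forcing periods
#'
#' Runs [run_forced()] at each forcing period in `p_grid` and classifies
#' the response with [classify_entrainment()].  Entrained intervals
#' separated by non-entrained gaps are the typical outcome.
#'
#' @inheritParams run_forced
#' @inheritParams classify_entrainment
#' @param p_grid Strictly increasing vector of forcing periods.
#' @return Data frame with one row per period: `p`, `status`, `K`,
#'   `phase_spread`.
#' @export
scan_periods <- function(g, lags, delta, p_grid, force_vertex = 1L,
                         probe_vertex = force_vertex, k_max = 8L, tol = 1.0,
                         tail_fraction = 0.25, max_spikes = 100000L) {
  stopifnot(length(p_grid) >= 1, all(diff(p_grid) > 0), all(p_grid > 0))
  rows <- lapply(p_grid, function(p) {
    h <- run_forced(g, lags, delta, p, force_vertex = force_vertex,
                    max_spikes = max_spikes)
    r <- classify_entrainment(h, p, probe_vertex = probe_vertex,
                              k_max = k_max, tol = tol,
                              tail_fraction = tail_fraction)
    data.frame(p = p, status = r$status, K = r$K,
               phase_spread = r$phase_spread)
  })
  do.call(rbind, rows)
}
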