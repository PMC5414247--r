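# Size survey of the embedding dimension: sample the conditional
# distribution P(m | n, X) over random z-regular SCGs at several network
# sizes, where X collects everything held fixed (z, delta, lag bounds, k).

#' Survey the embedding dimension across network sizes
#'
#' For each size `n` and replicate: derive a child seed from the master
#' seed, sample a strongly connected z-regular digraph
#' ([generate_scg()]), draw i.i.d. uniform lags ([assign_lags()]), run the
#' free dynamic kicked at vertex 1 ([run_free()]), and — if the run
#' sustains enough activity — estimate the embedding dimension of the
#' inter-spike-interval sequence at vertex 1 ([embedding_dimension()]).
#' Runs whose probe vertex accumulates fewer than `min_intervals`
#' post-burn-in intervals (e.g. because activity died out) are recorded
#' with `survived = FALSE` and no `m`.  Fully deterministic given `seed`;
#' any `(n, replicate)` subset reproduces independently because child
#' seeds depend only on `(seed, n, replicate)`.
#'
#' Defaults mirror the survey conditions: refractory period `delta = 30`,
#' degree `z = 3`, lags uniform on `[50, 100]`, window `k = 80`.
#'
#' @param n_values Integer vector of network sizes.
#' @param replicates Replicates per size, default 100.
#' @param z In/out degree of every vertex.
#' @param delta Refractory period.
#' @param lag_low,lag_high Uniform lag bounds.
#' @param k SSA window length.
#' @param burn_in Fraction of each vertex's spikes discarded before
#'   analysis.
#' @param min_intervals Minimum post-burn-in interval count required at the
#'   probe vertex, default `5 * (k + 1)`.
#' @param target_intervals Post-burn-in interval budget at the probe
#'   vertex, identical at every `n` so the observation length is part of
#'   the fixed conditions `X`.  Default 2000 (25 times the default window
#'   `k = 80`; weak spectral components need runs of this order to rise
#'   above the numerical floor).  The spike cap of each run is sized from
#'   it.
#' @param n_swaps Swap attempts per graph; default `100 * n * z` (about
#'   100 attempts per edge, the usual mixing budget for degree-preserving
#'   edge-swap randomisation).
#' @param seed Master seed.
#' @return Data frame of survey records: `n`, `rep`, `seed`, `m`,
#'   `significant`, `diameter`, `mean_isi`, `survived`.
#' @export
run_survey <- function(n_values, replicates = 100L, z = 3L, delta = 30,
                       lag_low = 50, lag_high = 100, k = 80L,
                       burn_in = 0.2, min_intervals = 5L * (k + 1L),
                       target_intervals = 2000L, n_swaps = NULL, seed = 1L) {
  stopifnot(replicates >= 1L, all(n_values > z),
            target_intervals >= min_intervals)
  # spikes needed so the probe vertex keeps ~target_intervals intervals
  # after burn-in; vertices fire at equal long-run rates, 25% margin
  need_per_vertex <- ceiling((target_intervals + 1L) / (1 - burn_in)) + 2L
  rows <- list()
  for (n in as.integer(n_values)) {
    swaps <- if (is.null(n_swaps)) 100L * n * z else as.integer(n_swaps)
    cap <- as.integer(ceiling(1.25 * n * need_per_vertex))
    for (rep_i in seq_len(replicates)) {
      seed_g <- child_seed(seed, n, rep_i, 1L)
      seed_l <- child_seed(seed, n, rep_i, 2L)
      g <- generate_scg(n, z, n_swaps = swaps, seed = seed_g)
      lags <- assign_lags(g, lag_low, lag_high, seed = seed_l)
      h <- run_free(g, lags, delta, kick = 1L, max_spikes = cap)
      probe <- spike_times(h, 1L)
      kept <- length(probe) - floor(burn_in * length(probe))
      survived <- kept - 1L >= min_intervals
      rec <- data.frame(n = n, rep = rep_i, seed = seed_g,
                        m = NA_integer_, significant = NA,
                        diameter = graph_diameter(g),
                        mean_isi = NA_real_, survived = survived)
      if (survived) {
        q <- interspike_intervals(h, 1L, burn_in)
        est <- embedding_dimension(q, k)
        rec$m <- est$m
        rec$significant <- est$significant
        rec$mean_isi <- mean(q)
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}

#' Five-number summary of the surveyed embedding dimension
#'
#' Median, quartiles (linear interpolation) and range of `m` per network
#' size over the surviving records — the numbers a box-and-whisker display
#' of `P(m | n, X)` shows.
#'
#' @param records Data frame from [run_survey()].
#' @return Data frame with one row per `n`: `n`, `count`, `median`, `q1`,
#'   `q3`, `min`, `max`.  Sizes with no surviving records get `count = 0`
#'   and `NA` summaries.
#' @export
summarize_survey <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("n", "m", "survived") %in% names(records)))
  rows <- lapply(split(records, records$n), function(d) {
    m <- d$m[d$survived]
    if (length(m) == 0L) {
      data.frame(n = d$n[1L], count = 0L, median = NA_real_, q1 = NA_real_,
                 q3 = NA_real_, min = NA_real_, max = NA_real_)
    } else {
      qs <- quantile(m, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(n = d$n[1L], count = length(m), median = qs[2L],
                 q1 = qs[1L], q3 = qs[3L], min = min(m), max = max(m))
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$n), , drop = FALSE]
}
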