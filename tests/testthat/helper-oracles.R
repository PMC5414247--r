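# Independent oracles and small fixture generators used across the suite.
# Everything here is deliberately written along a different route from the
# package code it checks.

# Random digraph on n vertices: each ordered pair gets an edge with
# probability p.  Not necessarily strongly connected.
random_digraph <- function(n, p = 0.4) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  scg_graph(n, as.matrix(pairs[keep, , drop = FALSE]))
}

# Random strongly connected z-regular graph with lags that are exact
# multiples of 0.25 in [low, high] (exactly representable in binary, so
# event-time sums and refractory boundaries are exact).
random_scg_fixture <- function(n, z, seed, low = 50, high = 100) {
  g <- generate_scg(n, z, n_swaps = 50L * n * z, seed = seed)
  lags <- with_quarter_lags(nrow(g$edges), low, high, seed + 1L)
  list(graph = g, lags = lags)
}

with_quarter_lags <- function(m, low, high, seed) {
  set.seed(seed)
  low + sample.int((high - low) * 4 + 1, m, replace = TRUE) / 4 - 0.25
}

# Brute-force fine-grid time-stepping simulator (dt = 1e-3 by default).
# Advances tick by tick; arrivals are delivered at their tick, targets are
# processed in ascending vertex order, and a vertex fires unless it is
# within D ticks of its own last spike (half-open window).  Independent of
# the event-driven core: no priority queue, integer tick arithmetic.
grid_simulate <- function(g, lags, delta, kick = 1L, max_spikes = 100L,
                          t_end = 1000, dt = 1e-3) {
  n <- g$n
  nt <- as.integer(round(t_end / dt))
  L <- as.integer(round(lags / dt))
  D <- as.integer(round(delta / dt))
  stopifnot(max(abs(L * dt - lags)) < 1e-9)  # lags must sit on the grid
  out_edges <- split(seq_len(nrow(g$edges)), g$edges[, 1L])
  pend <- vector("list", nt + 1L)
  pend[[1L]] <- as.integer(kick)
  last <- rep(NA_integer_, n)
  times <- integer(0)
  verts <- integer(0)
  for (tick in 0:nt) {
    arr <- pend[[tick + 1L]]
    if (is.null(arr)) next
    for (v in sort(arr)) {
      if (is.na(last[v]) || tick >= last[v] + D) {
        last[v] <- tick
        times <- c(times, tick)
        verts <- c(verts, v)
        for (e in out_edges[[as.character(v)]]) {
          idx <- tick + L[e] + 1L
          if (idx <= nt + 1L) {
            pend[[idx]] <- c(pend[[idx]], g$edges[e, 2L])
          }
        }
        if (length(times) >= max_spikes) {
          return(list(time = times * dt, vertex = verts))
        }
      }
    }
  }
  list(time = times * dt, vertex = verts)
}

# Eigenvalues of the window second-moment matrix via singular values of the
# trajectory matrix — an independent route from the package's
# eigen(crossprod()) path.
svd_spectrum_oracle <- function(q, k) {
  n_rows <- length(q) - k + 1
  X <- matrix(0, n_rows, k)
  for (i in seq_len(n_rows)) X[i, ] <- q[i:(i + k - 1)]
  svd(X / sqrt(n_rows), nu = 0, nv = 0)$d^2
}

# All-pairs shortest directed paths by Floyd-Warshall.
floyd_warshall_diameter <- function(g) {
  n <- g$n
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[g$edges] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  max(d)
}

# Quasi-periodic interval fixture: r incommensurate sinusoids around a
# positive offset.
sinusoid_intervals <- function(r, n_points = 2000, offset = 10) {
  freqs <- c(0.618034, 0.414214, 0.259921, 0.176091, 0.110001)[seq_len(r)]
  t <- seq_len(n_points)
  q <- rep(offset, n_points)
  for (f in freqs) q <- q + sin(2 * pi * f * t)
  q
}
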