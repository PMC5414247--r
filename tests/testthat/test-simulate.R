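two_loop <- function() scg_graph(2, rbind(c(1, 2), c(2, 1)))

test_that("two-vertex loop fires with period equal to the lag sum", {
  h <- run_free(two_loop(), c(50, 60), delta = 20, max_spikes = 9)
  expect_identical(spike_times(h, 1), c(0, 110, 220, 330, 440))
  expect_identical(spike_times(h, 2), c(50, 160, 270, 380))
  expect_identical(h$status, "reached_cap")
  expect_identical(unique(interspike_intervals(h, 1)), 110)
})

test_that("activity dies out when the return arrival is refractory", {
  h <- run_free(two_loop(), c(5, 5), delta = 20, max_spikes = 100)
  expect_identical(h$time, c(0, 5))
  expect_identical(h$vertex, c(1L, 2L))
  expect_identical(h$status, "died_out")
})

test_that("an isolated vertex spikes once and dies out", {
  h <- run_free(scg_graph(1), numeric(0), delta = 20, max_spikes = 10)
  expect_identical(h$time, 0)
  expect_identical(h$status, "died_out")
})

test_that("directed cycles sustain iff the lag sum reaches delta", {
  # ISI equals the cycle lag sum when it sustains; exactly L spikes when
  # the return arrival lands inside the refractory window; the boundary
  # S == delta fires (half-open window)
  for (L in 2:6) {
    g <- scg_graph(L, cbind(1:L, c(seq_len(L - 1) + 1L, 1L)))
    lags <- seq(2, length.out = L, by = 1)
    S <- sum(lags)
    h_go <- run_free(g, lags, delta = S - 0.5, max_spikes = 8 * L)
    expect_identical(h_go$status, "reached_cap")
    for (v in seq_len(L)) {
      expect_equal(unique(interspike_intervals(h_go, v)), S)
    }
    h_die <- run_free(g, lags, delta = S + 0.5, max_spikes = 8 * L)
    expect_identical(h_die$status, "died_out")
    expect_length(h_die$time, L)
    h_edge <- run_free(g, lags, delta = S, max_spikes = 3 * L)
    expect_identical(h_edge$status, "reached_cap")
    expect_equal(unique(interspike_intervals(h_edge, 1)), S)
  }
})

test_that("forced runs follow the hand-derived schedules", {
  # forcing at the free period locks 1:1 from the start
  h <- run_forced(two_loop(), c(50, 60), delta = 20, p = 110, max_spikes = 9)
  expect_identical(spike_times(h, 1), c(0, 110, 220, 330, 440))
  # pulses inside the refractory window are swallowed: p = 10 < delta = 20
  h2 <- run_forced(scg_graph(1), numeric(0), delta = 20, p = 10,
                   max_spikes = 6)
  expect_identical(h2$time, c(0, 20, 40, 60, 80, 100))
  # p = 25 > delta: every pulse fires
  h3 <- run_forced(scg_graph(1), numeric(0), delta = 20, p = 25,
                   max_spikes = 5)
  expect_identical(h3$time, c(0, 25, 50, 75, 100))
})

test_that("interspike_intervals applies burn-in by spike count", {
  h <- spike_history(c(0, 110, 220, 330), rep(1L, 4), n = 1,
                     status = "reached_cap")
  expect_identical(interspike_intervals(h, 1, 0), c(110, 110, 110))
  expect_identical(interspike_intervals(h, 1, 0.25), c(110, 110))
  expect_identical(interspike_intervals(h, 1, 0.5), 110)  # drops 2, keeps 2
  h2 <- spike_history(c(0, 110, 220), rep(1L, 3), n = 1,
                      status = "reached_cap")
  expect_error(interspike_intervals(h2, 1, 0.67), "fewer than 2")
})

test_that("mean ISI per vertex matches the analytic cycles", {
  h <- run_free(two_loop(), c(50, 60), delta = 20, max_spikes = 20)
  expect_equal(mean_isi(h), c(110, 110))
  g3 <- scg_graph(3, rbind(c(1, 2), c(2, 3), c(3, 1)))
  h3 <- run_free(g3, c(50, 60, 70), delta = 20, max_spikes = 30)
  expect_equal(mean_isi(h3), c(180, 180, 180))
})

test_that("refractory invariant and monotone event order hold on random runs", {
  for (s in 1:20) {
    fx <- random_scg_fixture(n = sample(4:10, 1), z = 2, seed = 1000 + s)
    delta <- sample(c(20, 30), 1)
    h <- run_free(fx$graph, fx$lags, delta, max_spikes = 400)
    expect_false(is.unsorted(h$time))
    for (v in seq_len(fx$graph$n)) {
      tt <- spike_times(h, v)
      if (length(tt) >= 2) expect_true(all(diff(tt) >= delta))
    }
  }
})

test_that("every spike traces back to an upstream spike plus the edge lag", {
  fx <- random_scg_fixture(n = 8, z = 2, seed = 314)
  h <- run_free(fx$graph, fx$lags, delta = 25, max_spikes = 300)
  edges <- fx$graph$edges
  for (i in seq_along(h$time)) {
    t <- h$time[i]; v <- h$vertex[i]
    if (t == 0) { expect_identical(v, 1L); next }
    into <- which(edges[, 2L] == v)
    parents <- vapply(into, function(e) {
      u <- edges[e, 1L]
      any(spike_times(h, u) == t - fx$lags[e])
    }, logical(1))
    expect_true(any(parents), info = sprintf("spike %d", i))
  }
})

test_that("event-driven spikes equal the fine-grid oracle on small graphs", {
  # a scaled-down version of the full equivalence sweep in the acceptance
  # suite: identical spike-for-spike output on seeded small SCGs
  for (s in 1:10) {
    set.seed(s)
    fx <- random_scg_fixture(n = sample(3:8, 1), z = 2, seed = 2000 + s)
    delta <- sample(c(20, 30), 1)
    h <- run_free(fx$graph, fx$lags, delta, max_spikes = 40, t_max = 600)
    o <- grid_simulate(fx$graph, fx$lags, delta, max_spikes = 40,
                       t_end = 600)
    expect_equal(h$time, o$time, tolerance = 1e-9)
    expect_identical(h$vertex, o$vertex)
  }
})

test_that("simulation input validation catches malformed configurations", {
  g <- two_loop()
  expect_error(run_free(g, c(50), delta = 20), "one delay per edge")
  expect_error(run_free(g, c(50, -1), delta = 20), "positive")
  expect_error(run_free(g, c(50, 60), delta = 0), "delta")
  expect_error(run_free(g, c(50, 60), delta = 20, kick = 3), "out of range")
  expect_error(run_forced(g, c(50, 60), delta = 20, p = 0), "positive")
})
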