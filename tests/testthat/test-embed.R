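test_that("trajectory matrix has the Hankel structure", {
  X <- trajectory_matrix(c(1, 2, 3, 4), k = 2)
  expect_identical(X, matrix(c(1, 2, 3, 2, 3, 4), 3, 2))
  Xc <- trajectory_matrix(rep(7, 10), k = 4)
  expect_true(all(Xc == 7))
  expect_identical(dim(Xc), c(7L, 4L))
  expect_error(trajectory_matrix(1:10, k = 10), "at least k \\+ 1")
})

test_that("a constant interval sequence is rank one with lambda_1 = k c^2", {
  s <- isi_spectrum(trajectory_matrix(rep(3, 100), k = 8))
  expect_equal(s$values[1], 8 * 9, tolerance = 1e-12)
  expect_lt(s$values[2] / s$values[1], 1e-12)
  est <- detect_break(s)
  expect_identical(est$m, 1L)
  expect_true(est$significant)
})

test_that("spectrum matches the SVD oracle and SSA sinusoid ranks", {
  t <- 1:2000
  q1 <- sin(2 * pi * 0.618034 * t)
  s <- isi_spectrum(trajectory_matrix(q1, k = 80))
  oracle <- svd_spectrum_oracle(q1, 80)
  expect_equal(s$values, oracle, tolerance = 1e-8)
  # a single sinusoid spans exactly two empirical orthogonal directions
  expect_identical(sum(s$values > 1e-6 * s$values[1]), 2L)

  q3 <- sinusoid_intervals(3)
  s3 <- isi_spectrum(trajectory_matrix(q3, k = 80))
  expect_identical(sum(s3$values > 1e-6 * s3$values[1]), 7L)
  expect_equal(s3$values, svd_spectrum_oracle(q3, 80), tolerance = 1e-8)
})

test_that("break detection: dominant gap, plateau tie rule, degenerate input", {
  fake <- function(values) structure(list(values = values,
                                          k = length(values),
                                          n_windows = 100L),
                                     class = "isi_spectrum")
  est <- detect_break(fake(c(100, 90, 80, rep(1e-9, 5))))
  expect_identical(est$m, 3L)
  expect_true(est$significant)
  # geometric spectrum: every gap equal and below theta -> earliest index,
  # flagged not significant (the noise-like decay case)
  est2 <- detect_break(fake(100 * 0.5^(0:9)))
  expect_identical(est2$m, 1L)
  expect_false(est2$significant)
  expect_error(detect_break(fake(rep(0, 8))), "degenerate")
})

test_that("embedding dimension recovers 2r + 1 for r sinusoids plus offset", {
  for (r in 1:3) {
    est <- embedding_dimension(sinusoid_intervals(r), k = 80)
    expect_identical(est$m, 2L * r + 1L)
    expect_true(est$significant)
  }
  # constant sequence: the attractor is a fixed interval, m = 1
  expect_identical(embedding_dimension(rep(5, 500), k = 80)$m, 1L)
  # perfectly periodic simulated system reduces to the constant case
  g3 <- scg_graph(3, rbind(c(1, 2), c(2, 3), c(3, 1)))
  h <- run_free(g3, c(50, 60, 70), delta = 20, max_spikes = 400)
  q <- interspike_intervals(h, 1, 0.2)
  expect_identical(embedding_dimension(q, k = 80)$m, 1L)
})

test_that("eigenvalues scale as c^2 and m is scale-invariant", {
  q <- sinusoid_intervals(2, n_points = 1200)
  for (c_ in c(0.5, 3, 17)) {
    s1 <- isi_spectrum(trajectory_matrix(q, 60))
    s2 <- isi_spectrum(trajectory_matrix(c_ * q, 60))
    expect_equal(s2$values, c_^2 * s1$values, tolerance = 1e-10)
    expect_identical(detect_break(s2)$m, detect_break(s1)$m)
  }
})

test_that("m never exceeds the numerical rank of the trajectory matrix", {
  set.seed(5)
  for (i in 1:10) {
    q <- sinusoid_intervals(sample(1:3, 1),
                            n_points = sample(500:1500, 1))
    X <- trajectory_matrix(q, 40)
    est <- detect_break(isi_spectrum(X))
    rank <- sum(svd(X, nu = 0, nv = 0)$d > 1e-8 * max(svd(X)$d))
    expect_lte(est$m, rank)
  }
})

test_that("heavy-tailed i.i.d. noise intervals show no significant break", {
  set.seed(31)
  flagged <- 0
  for (i in 1:100) {
    q <- rlnorm(800, meanlog = 0, sdlog = 2)
    est <- embedding_dimension(q, k = 60)
    if (est$significant) flagged <- flagged + 1
  }
  expect_lte(flagged, 10)
})
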