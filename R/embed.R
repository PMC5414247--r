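# Singular-spectrum estimation of an upper bound m on the attractor
# dimension from a scalar inter-spike-interval sequence.
#
# The interval sequence is window-embedded (delay 1 interval) into R^k; the
# eigenvalues of the uncentered k x k second-moment matrix of the windows
# give the partial variance along each empirical orthogonal direction, and
# the largest log-gap in the ordered eigenvalue list locates the
# signal/noise break.  The uncentered convention is deliberate: a purely
# periodic (constant-interval) system then gives m = 1, matching the
# reading of the attractor T^mu as embeddable in R^(mu+1).

#' Trajectory (lag-correlation) matrix of an interval sequence
#'
#' Stacks successive length-`k` windows of the sequence as rows: row `i` is
#' `(q_i, ..., q_(i+k-1))`, giving a Hankel matrix with
#' `N = length(q) - k + 1` rows.
#'
#' @param q Numeric vector of positive inter-spike intervals.
#' @param k Window length (embedding trial dimension), default 80.
#' @return An `N x k` numeric matrix.
#' @export
trajectory_matrix <- function(q, k = 80L) {
  k <- as.integer(k)
  if (k < 2L) stop("window length `k` must be at least 2", call. = FALSE)
  if (length(q) < k + 1L) {
    stop(sprintf("need at least k + 1 = %d intervals, got %d",
                 k + 1L, length(q)), call. = FALSE)
  }
  n_rows <- length(q) - k + 1L
  matrix(q[outer(seq_len(n_rows) - 1L, seq_len(k), "+")], n_rows, k)
}

#' Eigen-spectrum of the windowed second-moment matrix
#'
#' Eigenvalues of `C = X' X / N` where `X` is the trajectory matrix — the
#' uncentered second-moment matrix of the embedded point cloud.  All
#' eigenvalues are real and non-negative; tiny negatives from round-off are
#' clamped to zero.
#'
#' @param X A trajectory matrix from [trajectory_matrix()].
#' @return An object of class `isi_spectrum`: list with `values`
#'   (descending eigenvalues), `k`, and `n_windows`.
#' @export
isi_spectrum <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  C <- crossprod(X) / nrow(X)
  values <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  values[values < 0] <- 0
  structure(list(values = values, k = ncol(X), n_windows = nrow(X)),
            class = "isi_spectrum")
}

#' @export
print.isi_spectrum <- function(x, ...) {
  cat(sprintf("<isi_spectrum> k = %d, %d windows; leading eigenvalues:\n",
              x$k, x$n_windows))
  print(utils::head(signif(x$values, 4), 8))
  invisible(x)
}

#' Locate the spectral break
#'
#' Separates signal from noise in the ordered eigenvalue list.  Eigenvalues
#' below `floor_frac * lambda_1` are clamped to that floor, log-gaps
#' `log(lambda_i) - log(lambda_(i+1))` are formed for `1 <= i < k`, and `m`
#' is the *last* position whose gap exceeds `theta` — the final drop onto
#' the noise floor, below which no further structure stands out.  Taking
#' the last large gap rather than the global maximum matters because the
#' uncentered spectrum carries the (large) squared-mean component in
#' `lambda_1`: for a signal with small fluctuations about a large mean the
#' position-1 gap is always sizeable, and a global argmax would report
#' `m = 1` even when a clear multi-component structure breaks further out.
#' When no gap exceeds `theta` the spectrum is a gradual decay or plateau
#' (the signature of pink or white noise); the largest gap's position is
#' then reported with `significant = FALSE` (ties toward the smallest
#' index).
#'
#' @param s An `isi_spectrum`.
#' @param floor_frac Relative eigenvalue floor, default `1e-14`.  Symmetric
#'   eigendecomposition in double precision resolves eigenvalues down to
#'   roughly `k * eps` relative to the largest (about `2e-14` at `k = 80`);
#'   everything below is round-off and is clamped to the floor before the
#'   log-gaps are formed.
#' @param theta Significance threshold on the log-gap, in natural-log
#'   units; default 2.
#' @return An object of class `embedding_estimate`: list with `m`,
#'   `break_magnitude`, `significant`, and the attached `spectrum`.
#' @export
detect_break <- function(s, floor_frac = 1e-14, theta = 2) {
  stopifnot(inherits(s, "isi_spectrum"))
  lam <- s$values
  if (max(lam) <= 0) {
    stop("degenerate signal: all eigenvalues are zero", call. = FALSE)
  }
  lam <- pmax(lam, floor_frac * lam[1L])
  gaps <- diff(-log(lam))          # gaps[i] = log(lam[i]) - log(lam[i+1])
  big <- which(gaps > theta)
  # last drop onto the noise floor; plateau/decay spectra have no big gap
  m <- if (length(big)) big[length(big)] else which.max(gaps)
  structure(list(m = as.integer(m),
                 break_magnitude = gaps[m],
                 significant = gaps[m] > theta,
                 spectrum = s),
            class = "embedding_estimate")
}

#' @export
print.embedding_estimate <- function(x, ...) {
  cat(sprintf("<embedding_estimate> m = %d (log-gap %.2f, %s)\n",
              x$m, x$break_magnitude,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Embedding-dimension estimate from an interval sequence
#'
#' Composition of [trajectory_matrix()], [isi_spectrum()] and
#' [detect_break()]: the returned `m` is the estimated upper bound for the
#' dimension of the attractor underlying the interval sequence.
#' Deterministic given `q` and `k`.
#'
#' @inheritParams trajectory_matrix
#' @inheritParams detect_break
#' @return An `embedding_estimate`.
#' @examples
#' q <- 10 + sin(2 * pi * 0.618034 * (1:500))
#' embedding_dimension(q, k = 40)$m  # one sinusoid + offset: m = 3
#' @export
embedding_dimension <- function(q, k = 80L, floor_frac = 1e-14, theta = 2) {
  detect_break(isi_spectrum(trajectory_matrix(q, k)),
               floor_frac = floor_frac, theta = theta)
}
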