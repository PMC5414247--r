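# Sampling of z-regular strongly connected digraphs.
#
# Construction: superpose z edge-disjoint random Hamiltonian directed cycles
# (every vertex gets in-degree = out-degree = z and the graph is strongly
# connected by construction), then randomise by a degree-preserving
# double-edge-swap Markov chain that rejects any move breaking strong
# connectivity, so every graph along the chain stays irreducible.

#' Contrived z-regular seed graph
#'
#' Union of `z` edge-disjoint random Hamiltonian directed cycles on `n`
#' vertices.  Every vertex has in-degree and out-degree exactly `z`, and the
#' graph is strongly connected by construction (each cycle alone already is).
#' This is the deliberately contrived starting point of the edge-swap chain.
#'
#' @param n Vertex count.
#' @param z Target in/out degree, `1 <= z <= n - 1`.
#' @param seed Optional integer seed; when given, draws are made in a local
#'   RNG scope so the caller's RNG state is untouched.
#' @param max_tries Retry budget for finding an edge-disjoint cycle.
#' @return An `scg_graph` with `n * z` edges.
#' @export
seed_graph <- function(n, z, seed = NULL, max_tries = 200L) {
  if (z < 1 || z > n - 1) {
    stop("`z` must satisfy 1 <= z <= n - 1", call. = FALSE)
  }
  draw <- function() {
    seen <- new.env(hash = TRUE, size = as.integer(n * z * 2))
    edges <- matrix(0L, n * z, 2)
    row <- 0L
    for (j in seq_len(z)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        perm <- sample.int(n)
        from <- perm
        to <- c(perm[-1L], perm[1L])
        keys <- paste(from, to)
        if (!any(vapply(keys, exists, logical(1), envir = seen,
                        inherits = FALSE))) {
          for (key in keys) assign(key, TRUE, envir = seen)
          edges[row + seq_len(n), ] <- cbind(from, to)
          row <- row + n
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place %d edge-disjoint Hamiltonian cycles",
                     z), call. = FALSE)
      }
    }
    edges
  }
  edges <- if (is.null(seed)) draw() else with_seed(seed, draw())
  scg_graph(n, edges)
}

#' One degree-preserving edge-swap attempt
#'
#' Picks two distinct edges `(a, b)` and `(c, d)` uniformly at random and
#' proposes replacing them with `(a, d)` and `(c, b)` — a move that leaves
#' every in- and out-degree unchanged.  The proposal is rejected (the graph
#' is returned unmodified) when the endpoints coincide (`a == c`, `b == d`,
#' `a == d` or `c == b`), when either proposed edge already exists, or when
#' the swapped graph is no longer strongly connected.
#'
#' @param g A strongly connected `scg_graph`.
#' @return The (possibly unchanged) `scg_graph`, with attribute `"accepted"`
#'   set to `TRUE`/`FALSE`.
#' @export
edge_swap_step <- function(g) {
  stopifnot(inherits(g, "scg_graph"))
  m <- nrow(g$edges)
  if (m < 2L) {
    attr(g, "accepted") <- FALSE
    return(g)
  }
  idx <- sample.int(m, 2L)
  a <- g$edges[idx[1L], 1L]; b <- g$edges[idx[1L], 2L]
  c_ <- g$edges[idx[2L], 1L]; d <- g$edges[idx[2L], 2L]
  reject <- function(g) { attr(g, "accepted") <- FALSE; g }
  if (a == c_ || b == d || a == d || c_ == b) return(reject(g))
  key <- (as.double(g$edges[, 1L]) - 1) * g$n + as.double(g$edges[, 2L])
  if (((a - 1) * g$n + d) %in% key || ((c_ - 1) * g$n + b) %in% key) {
    return(reject(g))
  }
  new_edges <- g$edges
  new_edges[idx[1L], ] <- c(a, d)
  new_edges[idx[2L], ] <- c(c_, b)
  g2 <- scg_graph(g$n, new_edges)
  if (!is_strongly_connected(g2)) return(reject(g))
  attr(g2, "accepted") <- TRUE
  g2
}

#' Sample a strongly connected z-regular digraph
#'
#' Runs the full sampling chain: a [seed_graph()] of `z` superposed
#' Hamiltonian cycles followed by `n_swaps` degree-preserving edge-swap
#' attempts, each rejected unless the swapped graph stays strongly
#' connected.  The chain moves from the contrived seed towards more
#' homogeneous graphs, typically shrinking the diameter along the way.
#' Fully deterministic given `seed`.
#'
#' @param n Vertex count.
#' @param z In/out degree of every vertex.
#' @param n_swaps Number of swap *attempts* (rejections count; they are part
#'   of the Markov chain).  Default `100 * n * z`, about 100 attempts per
#'   edge — the usual mixing budget for edge-swap randomisation.
#' @param seed Integer seed for the chain (topology only; lags are drawn
#'   separately by [assign_lags()]).
#' @param snapshot_every If positive, also return the intermediate graph
#'   after every `snapshot_every` attempts (attribute `"snapshots"`, a list
#'   of edge matrices) for chain diagnostics.
#' @return An `scg_graph` with exactly `n * z` edges and all in/out degrees
#'   equal to `z`.
#' @examples
#' g <- generate_scg(20, 3, seed = 1)
#' graph_diameter(g)
#' @export
generate_scg <- function(n, z, n_swaps = 100L * n * z, seed = 1L,
                         snapshot_every = 0L) {
  g0 <- seed_graph(n, z, seed = seed)
  res <- swap_chain_cpp(as.integer(n), g0$edges - 1L, as.integer(n_swaps),
                        as.integer(seed), as.integer(snapshot_every))
  g <- scg_graph(n, res$edges + 1L)
  attr(g, "accepted_swaps") <- res$accepted
  if (snapshot_every > 0L) {
    attr(g, "snapshots") <- lapply(res$snapshots, function(e) e + 1L)
  }
  g
}

#' Assign i.i.d. uniform transmission lags
#'
#' Draws one independent `Uniform(low, high)` transmission delay per edge.
#' Lags are in the same (dimensionless) time units as the refractory period.
#'
#' @param g An `scg_graph`.
#' @param low,high Lag bounds, `0 < low <= high`.  `low == high` gives a
#'   degenerate (constant) lag.
#' @param seed Optional integer seed (local RNG scope).
#' @return A numeric vector of positive lags aligned with the rows of
#'   `g$edges`, with attribute `"bounds" = c(low, high)`.
#' @export
assign_lags <- function(g, low = 50, high = 100, seed = NULL) {
  stopifnot(inherits(g, "scg_graph"))
  if (!(high >= low && low > 0)) {
    stop("lag bounds must satisfy 0 < low <= high", call. = FALSE)
  }
  m <- nrow(g$edges)
  lags <- if (is.null(seed)) runif(m, low, high) else
    with_seed(seed, runif(m, low, high))
  attr(lags, "bounds") <- c(low, high)
  lags
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child-seed derivation (31-bit) so survey subsets are
# independently reproducible.  All intermediates stay below 2^53.
child_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (x in c(...)) {
    s <- (s * 48271 + as.double(x) * 16807 + 1) %% 2147483647
  }
  as.integer(s)
}
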