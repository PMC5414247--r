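#' Construct a directed graph
#'
#' Builds the directed-graph container used throughout the package: a vertex
#' count `n` and an edge list of ordered pairs.  Self-loops and duplicate
#' ordered pairs are rejected, so the adjacency matrix is 0/1 with a zero
#' diagonal.  Vertices are numbered `1..n`.
#'
#' @param n Positive integer vertex count.
#' @param edges Two-column integer matrix (or data frame) of directed edges,
#'   one `(from, to)` pair per row.  May have zero rows.
#' @return An object of class `scg_graph` with elements `n` and `edges`
#'   (an `m x 2` integer matrix with columns `from`, `to`).
#' @examples
#' g <- scg_graph(3, rbind(c(1, 2), c(2, 3), c(3, 1)))
#' is_strongly_connected(g)
#' @export
scg_graph <- function(n, edges = matrix(integer(0), 0, 2)) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L) {
    storage.mode(edges) <- "integer"
    if (ncol(edges) != 2L || anyNA(edges)) {
      stop("`edges` must be a two-column integer matrix without NAs",
           call. = FALSE)
    }
    if (any(edges < 1L) || any(edges > n)) {
      stop("edge endpoints must lie in 1..n", call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    key <- (as.double(edges[, 1L]) - 1) * n + as.double(edges[, 2L])
    if (anyDuplicated(key)) {
      stop("duplicate directed edges are not allowed", call. = FALSE)
    }
  } else {
    edges <- matrix(integer(0), 0, 2)
  }
  dimnames(edges) <- list(NULL, c("from", "to"))
  structure(list(n = n, edges = edges), class = "scg_graph")
}

#' @export
print.scg_graph <- function(x, ...) {
  cat(sprintf("<scg_graph> %d vertices, %d directed edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' @rdname scg_graph
#' @param g An `scg_graph`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "scg_graph"))
  ig <- igraph::graph_from_edgelist(g$edges, directed = TRUE)
  if (igraph::vcount(ig) < g$n) {
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  }
  ig
}

#' Adjacency matrix of a directed graph
#'
#' @param g An `scg_graph`.
#' @return A dense 0/1 integer matrix `A` with `A[i, j] = 1` iff the edge
#'   `(i, j)` is present.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "scg_graph"))
  A <- matrix(0L, g$n, g$n)
  if (nrow(g$edges)) A[g$edges] <- 1L
  A
}

#' Test strong connectivity
#'
#' A directed graph is strongly connected when every vertex can reach every
#' other vertex by a directed walk; equivalently its adjacency matrix is
#' irreducible.  The check runs one forward and one backward graph search
#' from vertex 1 (two depth-first-search passes).
#'
#' @param g An `scg_graph`.
#' @return `TRUE` or `FALSE`.  A single-vertex graph is strongly connected.
#' @seealso [irreducibility_oracle()] for the matrix-power criterion.
#' @export
is_strongly_connected <- function(g) {
  stopifnot(inherits(g, "scg_graph"))
  if (g$n == 1L) return(TRUE)
  if (nrow(g$edges) == 0L) return(FALSE)
  ig <- igraph::graph_from_edgelist(g$edges, directed = TRUE)
  if (igraph::vcount(ig) < g$n) return(FALSE)  # isolated trailing vertices
  igraph::is_connected(ig, mode = "strong")
}

#' Irreducibility criterion via adjacency powers
#'
#' Checks strong connectivity through the algebraic criterion: the adjacency
#' matrix `A` is irreducible iff every entry of `I + A + A^2 + ... + A^(n-1)`
#' is strictly positive (a walk of length below `n` joins every ordered
#' vertex pair).  Quadratic-to-cubic in `n`; intended as an independent
#' cross-check of [is_strongly_connected()] on small graphs.
#'
#' @param g An `scg_graph`.
#' @return `TRUE` or `FALSE`.
#' @export
irreducibility_oracle <- function(g) {
  stopifnot(inherits(g, "scg_graph"))
  n <- g$n
  if (n == 1L) return(TRUE)
  A <- adjacency_matrix(g)
  # walk-existence booleans, not counts, to avoid overflow
  S <- diag(n) > 0
  P <- diag(n) > 0
  for (k in seq_len(n - 1L)) {
    P <- (P %*% A) > 0
    S <- S | P
  }
  all(S)
}

#' Directed diameter
#'
#' The maximum over ordered vertex pairs of the shortest directed path
#' length (unweighted).
#'
#' @param g A strongly connected `scg_graph`.
#' @return Integer diameter (0 for a single vertex).
#' @export
graph_diameter <- function(g) {
  stopifnot(inherits(g, "scg_graph"))
  if (g$n == 1L) return(0L)
  if (!is_strongly_connected(g)) {
    stop("graph is not strongly connected: diameter is infinite",
         call. = FALSE)
  }
  ig <- igraph::graph_from_edgelist(g$edges, directed = TRUE)
  d <- igraph::distances(ig, mode = "out")
  as.integer(max(d))
}
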