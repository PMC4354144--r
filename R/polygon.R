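#' Closed and open polygonal chains
#'
#' A `polygon3` is an ordered set of 3-D vertices joined cyclically by straight
#' segments; an `open_chain` is the same without the closing segment.  These two
#' records are the geometric substrate of every topological operation in the
#' package: closed chains are classified directly, open chains through the
#' stochastic closure protocol.
#'
#' Vertex indices are 0-based throughout the package (subchain starts, scission
#' positions, matrix cells), so that the subchain `(start, nseg)` covers
#' vertices `start, start+1, ..., start+nseg` modulo `n`.
#'
#' @param vertices a numeric matrix with 3 columns (x, y, z), one row per
#'   vertex, or a data frame with columns `x`, `y`, `z`.
#' @param tol relative tolerance used to reject coincident consecutive
#'   vertices.
#' @return `polygon3()` returns an object of class `polygon3`; `open_chain()`
#'   an object of class `open_chain`.  Both are numeric matrices with an
#'   attribute-based class, so `nrow()` gives the vertex count.
#' @examples
#' sq <- polygon3(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0))
#' n_segments(sq)
#' @export
polygon3 <- function(vertices, tol = 1e-9) {
  v <- as_vertex_matrix(vertices)
  if (nrow(v) < 3) abort("a closed polygon needs at least 3 vertices")
  check_consecutive(v, closed = TRUE, tol = tol)
  structure(v, class = c("polygon3", "matrix", "array"))
}

#' @rdname polygon3
#' @export
open_chain <- function(vertices, tol = 1e-9) {
  v <- as_vertex_matrix(vertices)
  if (nrow(v) < 2) abort("an open chain needs at least 2 vertices (1 segment)")
  check_consecutive(v, closed = FALSE, tol = tol)
  structure(v, class = c("open_chain", "matrix", "array"))
}

as_vertex_matrix <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices[, c("x", "y", "z")])
  v <- unclass(vertices)
  storage.mode(v) <- "double"
  if (!is.matrix(v) || ncol(v) != 3) abort("vertices must be an n x 3 matrix")
  dimnames(v) <- NULL
  v
}

check_consecutive <- function(v, closed, tol) {
  idx <- if (closed) rbind(seq_len(nrow(v)), c(seq_len(nrow(v))[-1], 1L))
  else rbind(seq_len(nrow(v) - 1L), seq_len(nrow(v))[-1])
  d <- sqrt(rowSums((v[idx[1, ], , drop = FALSE] - v[idx[2, ], , drop = FALSE])^2))
  scale <- max(1e-300, max(abs(v)))
  if (any(d <= tol * scale))
    abort(paste0("coincident consecutive vertices at position ",
                 which(d <= tol * scale)[1] - 1L))
  invisible(v)
}

#' @rdname polygon3
#' @param x a `polygon3` or `open_chain`.
#' @export
n_segments <- function(x) {
  if (inherits(x, "polygon3")) nrow(x) else nrow(x) - 1L
}

#' @export
print.polygon3 <- function(x, ...) {
  cat("<polygon3> closed chain,", nrow(x), "vertices /", n_segments(x), "segments\n")
  invisible(x)
}

#' @export
print.open_chain <- function(x, ...) {
  cat("<open_chain>", nrow(x), "vertices /", n_segments(x), "segments\n")
  invisible(x)
}

#' @export
as_tibble.polygon3 <- function(x, ...) {
  v <- unclass(x)
  tibble::tibble(vertex = seq_len(nrow(v)) - 1L,
                 x = v[, 1], y = v[, 2], z = v[, 3])
}

#' @export
as_tibble.open_chain <- as_tibble.polygon3

#' Extract a subchain of a closed polygon
#'
#' Takes `nseg` consecutive segments starting at vertex `start` (0-based),
#' walking circularly, and returns them as an open chain of `nseg + 1`
#' vertices.  The full polygon (`nseg = n`) is excluded: a subchain is always a
#' proper arc.
#'
#' @param polygon a [polygon3()] with `n` segments.
#' @param start 0-based index of the first vertex, `0 <= start < n`.
#' @param nseg number of segments, `1 <= nseg <= n - 1`.
#' @return an [open_chain()].
#' @examples
#' p <- torus_knot_polygon(2, 3, 47)
#' make_subchain(p, start = 46, nseg = 2)   # wraps around vertex 0
#' @export
make_subchain <- function(polygon, start, nseg) {
  stopifnot(inherits(polygon, "polygon3"))
  n <- n_segments(polygon)
  if (start < 0 || start >= n) abort("start must lie in [0, n)")
  if (nseg < 1 || nseg > n - 1)
    abort(paste0("nseg must lie in [1, n-1]; nseg = n would be the closed ",
                 "polygon, not a subchain"))
  idx <- (start + 0:nseg) %% n + 1L
  out <- open_chain(unclass(polygon)[idx, , drop = FALSE])
  attr(out, "start") <- as.integer(start)
  out
}

#' Subdivide every segment of a chain
#'
#' Replaces each segment by `k` collinear segments of equal length.  The
#' geometric trace, and hence the knot type, is unchanged; only the vertex
#' resolution increases, which matters when a subchain analysis needs to cut at
#' finer positions.
#'
#' @param x a [polygon3()] or [open_chain()].
#' @param k integer subdivision factor, `k >= 2`.
#' @return an object of the same class with `k` times as many segments.
#' @export
refine <- function(x, k) {
  stopifnot(k >= 2, k == round(k))
  v <- unclass(x)
  n <- nrow(v)
  closed <- inherits(x, "polygon3")
  nxt <- if (closed) c(2:n, 1L) else c(2:n, n)  # last row unused when open
  nedge <- if (closed) n else n - 1L
  out <- matrix(0, nedge * k + (!closed), 3)
  row <- 1L
  for (i in seq_len(nedge)) {
    a <- v[i, ]
    b <- v[nxt[i], ]
    for (j in 0:(k - 1)) {
      out[row, ] <- a + (b - a) * j / k
      row <- row + 1L
    }
  }
  if (!closed) out[row, ] <- v[n, ]
  if (closed) polygon3(out) else open_chain(out)
}

#' Parametric torus-knot polygon
#'
#' Equally spaced samples of the standard (p, q) torus-knot curve on a torus
#' with major radius 2 and minor radius 1, closed into a polygon.  These highly
#' regular configurations serve as reference hosts whose subknot structure is
#' known: the (2, 3) polygon is a trefoil, the (2, 5) a 5_1, and so on.
#'
#' @param p,q coprime integers, both at least 2.
#' @param nseg number of segments; at least ~6 q samples are needed for the
#'   polygon to be an honest embedding of the curve (>= 12 for the trefoil).
#' @return a [polygon3()].
#' @export
torus_knot_polygon <- function(p, q, nseg) {
  if (p < 2 || q < 2) abort("p and q must both be at least 2")
  if (gcd(p, q) != 1) abort("p and q must be coprime (otherwise the curve is a link)")
  t <- 2 * pi * (seq_len(nseg) - 1) / nseg
  polygon3(cbind((2 + cos(q * t)) * cos(p * t),
                 (2 + cos(q * t)) * sin(p * t),
                 sin(q * t)))
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Random equilateral polygon
#'
#' Samples a closed equilateral polygon with `n` unit-length edges: `n/2` edge
#' directions are drawn uniformly on the sphere and emitted together with their
#' antipodes (which forces exact closure), the 2 x (n/2) edge vectors are
#' randomly permuted, and the polygon is then decorrelated by `10 n` random
#' crankshaft rotations, each of which turns the arc between two random
#' vertices about the chord through them.  Crankshaft moves preserve both edge
#' lengths and closure exactly and are ergodic on equilateral polygon space, so
#' the sampled configurations approximate the uniform distribution on closed
#' equilateral n-gons.
#'
#' @param n even number of edges, `n >= 4`.
#' @param seed integer seed; the polygon is a deterministic function of
#'   `(n, seed)`.
#' @param n_crank number of crankshaft moves (default `10 * n`).
#' @return a [polygon3()] with `n` unit edges.
#' @export
random_equilateral_polygon <- function(n, seed, n_crank = 10L * n) {
  if (n %% 2 != 0)
    abort("n must be even: the antipodal-pair construction needs n/2 direction pairs")
  if (n < 4) abort("n must be at least 4")
  v <- with_seed(seed, .cpp_random_polygon(as.integer(n), as.integer(n_crank)))
  polygon3(v)
}

#' Lissajous knot polygon
#'
#' Equally spaced samples of a Lissajous curve
#' `(cos(n1 t + p1), cos(n2 t + p2), cos(n3 t + p3))`.  Lissajous curves with
#' pairwise coprime frequencies and generic phases are embedded closed
#' curves; suitable parameter choices realize twist knots such as 5_2 and
#' 6_1, complementing the torus-knot fixtures with hosts whose trimming
#' behaviour involves intermediate twist-knot types.  Two choices found by
#' classification sweep and frozen here: frequencies (2,3,7) with phases
#' (0.1, 0.55, 0) give a 5_2; frequencies (2,3,5) with phases (0.1, 1, 0)
#' give a 6_1.
#'
#' @param freq integer frequency triple.
#' @param phase numeric phase triple.
#' @param nseg number of segments.
#' @return a [polygon3()].
#' @export
lissajous_polygon <- function(freq, phase = c(0.1, 1, 0), nseg = 120) {
  stopifnot(length(freq) == 3, length(phase) == 3, nseg >= 12)
  t <- 2 * pi * (seq_len(nseg) - 1) / nseg
  polygon3(cbind(cos(freq[1] * t + phase[1]),
                 cos(freq[2] * t + phase[2]),
                 cos(freq[3] * t + phase[3])))
}
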