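#' Direction sets for the uniform closure protocol
#'
#' A direction set is a collection of unit 3-vectors with positive weights
#' summing to one.  Each open subchain is closed along every direction in the
#' set and the weight of a direction is the probability mass its closure
#' contributes to the knot-type spectrum of that subchain.
#'
#' `direction_set()` wraps an arbitrary matrix of directions.  When `weights`
#' is `NULL` they are computed as the fractional areas of the spherical
#' Voronoi cells of the direction set, so that a non-uniform set still samples
#' the sphere of closure directions without bias.
#'
#' @param directions an m x 3 numeric matrix of direction vectors (rows are
#'   normalized internally).
#' @param weights optional positive weights, recycled and normalized to sum 1.
#' @return a tibble with columns `x`, `y`, `z`, `weight` and class
#'   `direction_set`.
#' @export
direction_set <- function(directions, weights = NULL) {
  d <- as.matrix(directions)
  storage.mode(d) <- "double"
  if (ncol(d) != 3) abort("directions must be an m x 3 matrix")
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm <= 0)) abort("zero direction vector")
  d <- d / nrm
  # coincident directions make the Voronoi construction degenerate
  g <- tcrossprod(d)
  diag(g) <- -2
  if (max(g) >= 1 - 1e-12)
    abort("coincident directions in the set")
  if (is.null(weights)) {
    weights <- spherical_voronoi_weights(d)
  } else {
    if (any(weights <= 0)) abort("weights must be positive")
    weights <- rep_len(weights, nrow(d))
    weights <- weights / sum(weights)
  }
  out <- tibble::tibble(x = d[, 1], y = d[, 2], z = d[, 3], weight = weights)
  class(out) <- c("direction_set", class(out))
  out
}

#' @rdname direction_set
#' @details `dodecahedron_directions()` returns the 20 vertices of a regular
#'   dodecahedron, each carrying weight exactly 0.05; the set is perfectly
#'   uniform and closed under the antipodal map.
#' @export
dodecahedron_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  cube <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  a <- 1 / phi
  rect <- rbind(cbind(0, c(-a, -a, a, a), c(-phi, phi, -phi, phi)),
                cbind(c(-a, -a, a, a), c(-phi, phi, -phi, phi), 0),
                cbind(c(-phi, phi, -phi, phi), 0, c(-a, -a, a, a)))
  v <- rbind(unname(cube), rect)
  direction_set(v, weights = rep(0.05, 20))
}

#' @rdname direction_set
#' @param n number of directions (at least 4).
#' @param seed integer seed; the set is a deterministic function of
#'   `(n, seed)`.
#' @details `uniform_directions()` builds a roughly uniform n-point set (a
#'   Fibonacci sphere lattice under a seeded random rotation) and weights each
#'   direction by the fraction of the sphere its Voronoi cell occupies.
#' @export
uniform_directions <- function(n, seed = 1L) {
  if (n < 4) abort("need at least 4 directions")
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  ga <- pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(ga * i), r * sin(ga * i), z)
  rot <- with_seed(seed, random_rotation())
  direction_set(pts %*% rot)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed, det +1
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Fractional spherical Voronoi cell areas.
#
# The cell of direction d_i is the intersection of the hemispheres
# {x : x.d_i >= x.d_j}.  Under the gnomonic projection centred at d_i each
# bounding great circle becomes a straight line, so the cell maps to a convex
# planar polygon obtained by half-plane clipping; mapping its corners back to
# the sphere, the cell area is the sum of spherical triangle areas of the fan
# around d_i (L'Huilier).  Areas are validated to sum to 4*pi.
spherical_voronoi_weights <- function(d, clip_radius = 60) {
  m <- nrow(d)
  areas <- numeric(m)
  for (i in seq_len(m)) {
    di <- d[i, ]
    # tangent basis at di
    e <- diag(3)[, which.min(abs(di))]
    u <- e - sum(e * di) * di
    u <- u / sqrt(sum(u^2))
    v <- c(di[2] * u[3] - di[3] * u[2],
           di[3] * u[1] - di[1] * u[3],
           di[1] * u[2] - di[2] * u[1])
    R <- clip_radius
    poly <- rbind(c(-R, -R), c(R, -R), c(R, R), c(-R, R))
    for (j in seq_len(m)) {
      if (j == i) next
      w <- di - d[j, ]
      a0 <- sum(di * w)
      a1 <- sum(u * w)
      a2 <- sum(v * w)
      poly <- clip_halfplane(poly, a1, a2, a0)   # keep a0 + a1 x + a2 y >= 0
      if (is.null(poly)) break
    }
    if (is.null(poly) || nrow(poly) < 3) { areas[i] <- 0; next }
    corners <- t(apply(poly, 1, function(p) {
      x <- di + p[1] * u + p[2] * v
      x / sqrt(sum(x^2))
    }))
    areas[i] <- sum(vapply(seq_len(nrow(corners)), function(k) {
      spherical_triangle_area(di, corners[k, ], corners[k %% nrow(corners) + 1, ])
    }, numeric(1)))
  }
  total <- sum(areas)
  if (abs(total - 4 * pi) > 1e-6 * 4 * pi)
    abort("spherical Voronoi areas do not tile the sphere; direction set degenerate")
  areas / total
}

clip_halfplane <- function(poly, a1, a2, a0) {
  n <- nrow(poly)
  val <- a0 + poly[, 1] * a1 + poly[, 2] * a2
  if (all(val >= 0)) return(poly)
  if (all(val < 0)) return(NULL)
  out <- matrix(0, 0, 2)
  for (k in seq_len(n)) {
    k2 <- k %% n + 1
    in1 <- val[k] >= 0
    in2 <- val[k2] >= 0
    if (in1) out <- rbind(out, poly[k, ])
    if (xor(in1, in2)) {
      t <- val[k] / (val[k] - val[k2])
      out <- rbind(out, poly[k, ] + t * (poly[k2, ] - poly[k, ]))
    }
  }
  if (nrow(out) < 3) NULL else out
}

spherical_triangle_area <- function(a, b, c) {
  # L'Huilier's theorem
  sa <- acos(pmin(1, pmax(-1, sum(b * c))))
  sb <- acos(pmin(1, pmax(-1, sum(a * c))))
  sc <- acos(pmin(1, pmax(-1, sum(a * b))))
  s <- (sa + sb + sc) / 2
  x <- tan(s / 2) * tan((s - sa) / 2) * tan((s - sb) / 2) * tan((s - sc) / 2)
  4 * atan(sqrt(pmax(0, x)))
}

#' @export
print.direction_set <- function(x, ...) {
  cat("<direction_set>", nrow(x), "directions, weight range [",
      format(min(x$weight), digits = 4), ",",
      format(max(x$weight), digits = 4), "]\n")
  NextMethod()
}

direction_matrix <- function(dirs) {
  stopifnot(inherits(dirs, "direction_set"))
  cbind(dirs$x, dirs$y, dirs$z)
}
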