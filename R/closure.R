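#' Close an open chain along a direction
#'
#' Realizes the closure-at-infinity of an open chain in a given direction as a
#' finite polygon: two parallel rays of length `L` are attached to the chain's
#' endpoints along the direction and their tips joined by a segment.  `L` is
#' chosen as the chain's span along the direction plus three bounding-box
#' diameters times `(1 + hull_margin)`, which places both tips strictly beyond
#' every vertex in the closure direction -- hence outside the convex hull
#' scaled about its centroid by `(1 + hull_margin)` -- so the finite closure is
#' isotopic to the closure at infinity.
#'
#' If a ray passes within tolerance of an interior vertex (a genuine spatial
#' degeneracy), the direction is deterministically perturbed in steps growing
#' from 1e-6 radians and the perturbation is recorded in the `perturbed`
#' attribute.
#'
#' @param chain an [open_chain()].
#' @param direction 3-vector, normalized internally.
#' @param hull_margin non-negative margin factor (the classified knot type is
#'   independent of it).
#' @return a [polygon3()] with `n_segments(chain) + 3` edges.
#' @export
close_chain <- function(chain, direction, hull_margin = 0.5) {
  stopifnot(inherits(chain, "open_chain"))
  v <- unclass(chain)
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  n <- nrow(v)
  diam <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  if (diam <= 0) diam <- 1
  perturbed <- 0L
  repeat {
    proj <- v %*% d
    L <- max(proj) - min(proj[1], proj[n]) + 3 * diam * (1 + hull_margin)
    tip_b <- v[n, ] + L * d
    tip_a <- v[1, ] + L * d
    if (n == 2 || rays_clear(v, d, L, diam)) break
    if (perturbed >= 8L) abort("could not clear ray-vertex degeneracy")
    perturbed <- perturbed + 1L
    ax <- perp_axis(d)
    th <- 1e-6 * 8^(perturbed - 1)
    d <- d * cos(th) + ax * sin(th)
  }
  out <- polygon3(rbind(v, tip_b, tip_a))
  attr(out, "direction") <- d
  attr(out, "perturbed") <- perturbed
  out
}

rays_clear <- function(v, d, L, diam) {
  n <- nrow(v)
  for (base in c(n, 1L)) {
    w <- sweep(v[-c(1L, n), , drop = FALSE], 2, v[base, ])
    t <- as.numeric(w %*% d)
    perp2 <- rowSums(w^2) - t^2
    hit <- t >= 0 & t <= L & perp2 < (1e-9 * diam)^2
    if (any(hit)) return(FALSE)
  }
  TRUE
}

perp_axis <- function(d) {
  e <- diag(3)[, which.min(abs(d))]
  ax <- e - sum(e * d) * d
  ax / sqrt(sum(ax^2))
}

#' Knot-type spectrum of an open chain
#'
#' Closes the chain along every direction of a [direction_set()] and
#' accumulates each direction's weight onto the knot type of its closure,
#' giving the spectrum of the stochastic closure protocol.  Directions whose
#' closure cannot be classified even after the perturbation/retry ladder are
#' dropped and their weight redistributed proportionally; the number of such
#' failures is recorded in `attr(, "failures")` and warned about (it is zero
#' in normal operation).
#'
#' @param chain an [open_chain()].
#' @param dirs a [direction_set()]; defaults to the 20 dodecahedron vertices.
#' @param table a [build_knot_table()].
#' @param hull_margin passed to the closure construction.
#' @param view_seed seed for projection directions.
#' @param tol,budget,max_nodes identification pipeline controls, see
#'   [classify()].
#' @return a `knot_spectrum`: a tibble with columns `type`, `weight` (sorted
#'   by decreasing weight), attributes `nseg` and `failures`.
#' @export
closure_spectrum <- function(chain, dirs = dodecahedron_directions(),
                             table = build_knot_table(), hull_margin = 0.5,
                             view_seed = 1L, tol = 1e-9, budget = 200L,
                             max_nodes = 2e5) {
  stopifnot(inherits(chain, "open_chain"))
  res <- closure_types(unclass(chain), dirs, table, hull_margin, view_seed,
                       tol, budget, max_nodes)
  out <- new_spectrum(res$types, dirs$weight, res$failures, n_segments(chain))
  attr(out, "start") <- attr(chain, "start")
  out
}

# shared fast path: returns per-direction type names (NA on failure)
closure_types <- function(vmat, dirs, table, hull_margin, view_seed, tol,
                          budget, max_nodes) {
  viewdirs <- view_attempts(NULL, view_seed, 12L)
  r <- .cpp_closure_polys(vmat, direction_matrix(dirs), hull_margin, viewdirs,
                          tol, as.integer(budget), max_nodes)
  types <- rep(NA_character_, nrow(dirs))
  okk <- r$ok
  if (any(okk))
    types[okk] <- names_from_polys(r$poly[okk], r$bound[okk], table)
  list(types = types, failures = sum(!okk))
}

new_spectrum <- function(types, weights, failures, nseg) {
  ok <- !is.na(types)
  w <- weights[ok] / sum(weights[ok])
  agg <- tapply(w, types[ok], sum)
  out <- tibble::tibble(type = names(agg), weight = as.numeric(agg))
  out <- out[order(-out$weight, knot_crossing_number(out$type), out$type), ]
  class(out) <- c("knot_spectrum", class(out))
  attr(out, "nseg") <- nseg
  attr(out, "failures") <- failures
  if (failures > 0)
    warn(paste0(failures, " closure direction(s) could not be classified; ",
                "their weight was redistributed"))
  out
}

#' Dominant and majority knot types of a spectrum
#'
#' `dominant()` returns the heaviest type in the spectrum; ties are broken
#' first by smaller minimal crossing number, then lexicographically.
#' `majority_types()` returns the types holding at least half the closure
#' weight -- at most one type, since an exact 0.5/0.5 split is resolved by the
#' dominance tie-break so that the majority call stays single-valued.
#'
#' @param spectrum a `knot_spectrum` (or any tibble with `type`, `weight`).
#' @return `dominant()`: a list with elements `type` and `frequency`;
#'   `majority_types()`: a character vector of length 0 or 1.
#' @export
dominant <- function(spectrum) {
  if (nrow(spectrum) == 0) abort("empty spectrum")
  ord <- order(-spectrum$weight, knot_crossing_number(spectrum$type),
               spectrum$type)
  list(type = spectrum$type[ord[1]], frequency = spectrum$weight[ord[1]])
}

#' @rdname dominant
#' @export
majority_types <- function(spectrum) {
  if (nrow(spectrum) == 0) return(character(0))
  half <- spectrum$type[spectrum$weight >= 0.5]
  if (length(half) <= 1) return(half)
  dominant(spectrum)$type
}

#' @export
print.knot_spectrum <- function(x, ...) {
  cat("<knot_spectrum> of a", attr(x, "nseg"), "segment chain\n")
  NextMethod()
}
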