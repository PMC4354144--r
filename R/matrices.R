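#' Disk matrix of a closed polygonal knot
#'
#' Computes, for every proper subchain `(start, nseg)` of the polygon, the
#' dominant knot type of the stochastic closure spectrum and its frequency.
#' Geometrically the cells form a polar ("disk") arrangement: latitude is the
#' subchain length `nseg` (1 at the centre to `n - 1` at the rim), longitude is
#' the circular position of the subchain midpoint, `(start + nseg/2) mod n`,
#' whose half-integer grid produces the brick-wall pattern of alternating
#' rows.  An `n`-segment host yields exactly `n * (n - 1)` cells.
#'
#' @param polygon a [polygon3()].
#' @param dirs a [direction_set()] of closure directions.
#' @param table a [build_knot_table()].
#' @param spectra keep the full spectrum of every cell as a list column
#'   (memory-heavy for large hosts).
#' @param hull_margin,view_seed,tol,budget,max_nodes pipeline controls, see
#'   [closure_spectrum()] and [classify()].
#' @param progress print a progress line every 20 latitudes.
#' @return a `disk_matrix`: tibble with columns `start`, `nseg`, `longitude`,
#'   `knot`, `freq` (and `spectrum` if requested), attributes `n`,
#'   `global_type`, `failures`.
#' @export
disk_matrix <- function(polygon, dirs = dodecahedron_directions(),
                        table = build_knot_table(), spectra = FALSE,
                        hull_margin = 0.5, view_seed = 1L, tol = 1e-9,
                        budget = 200L, max_nodes = 2e5, progress = FALSE) {
  stopifnot(inherits(polygon, "polygon3"))
  n <- n_segments(polygon)
  v <- unclass(polygon)
  global <- as.character(classify(polygon, table = table, view_seed = view_seed))
  viewdirs <- view_attempts(NULL, view_seed, 12L)
  dmat <- direction_matrix(dirs)
  w <- dirs$weight
  ncell <- n * (n - 1L)
  starts <- integer(ncell); nsegs <- integer(ncell)
  knots <- character(ncell); freqs <- numeric(ncell)
  specs <- if (spectra) vector("list", ncell) else NULL
  failures <- 0L
  cell <- 0L
  for (k in seq_len(n - 1L)) {
    if (progress && k %% 20L == 0L) message("latitude ", k, " / ", n - 1L)
    for (s in 0:(n - 1L)) {
      cell <- cell + 1L
      idx <- (s + 0:k) %% n + 1L
      r <- .cpp_closure_polys(v[idx, , drop = FALSE], dmat, hull_margin,
                              viewdirs, tol, as.integer(budget), max_nodes)
      okk <- r$ok
      failures <- failures + sum(!okk)
      types <- names_from_polys(r$poly[okk], r$bound[okk], table)
      ww <- w[okk] / sum(w[okk])
      dom <- dominant_of(types, ww, table)
      starts[cell] <- s; nsegs[cell] <- k
      knots[cell] <- dom$type; freqs[cell] <- dom$frequency
      if (spectra) specs[[cell]] <- new_spectrum(types, w[okk], sum(!okk), k)
    }
  }
  out <- tibble::tibble(start = starts, nseg = nsegs,
                        longitude = (starts + nsegs / 2) %% n,
                        knot = knots, freq = freqs)
  if (spectra) out$spectrum <- specs
  class(out) <- c("disk_matrix", class(out))
  attr(out, "n") <- n
  attr(out, "global_type") <- global
  attr(out, "failures") <- failures
  if (failures > 0)
    warn(paste0(failures, " closure(s) failed to classify across the matrix"))
  out
}

# lean dominant: aggregate weights by type with the (crossing number, name)
# tie-break, avoiding tibble construction in the hot loop
dominant_of <- function(types, weights, table) {
  agg <- rowsum(weights, types)
  nms <- rownames(agg)
  ord <- order(-agg[, 1], cn_cached(nms, table), nms)
  list(type = nms[ord[1]], frequency = agg[ord[1], 1])
}

cn_cached <- function(nms, table) {
  env <- table$cache
  out <- integer(length(nms))
  for (i in seq_along(nms)) {
    key <- paste0("cn.", nms[i])
    hit <- get0(key, envir = env)
    if (is.null(hit)) {
      hit <- knot_crossing_number(nms[i])
      if (is.na(hit)) hit <- 999L   # unknown types sort last in tie-breaks
      assign(key, hit, envir = env)
    }
    out[i] <- hit
  }
  out
}

#' @export
print.disk_matrix <- function(x, ...) {
  cat("<disk_matrix> host:", attr(x, "n"), "segments, global type",
      attr(x, "global_type"), "\n")
  NextMethod()
}

#' Triangular matrix of an open chain
#'
#' The linear-chain analogue of [disk_matrix()], as used for knotted protein
#' backbones: one cell per contiguous subchain `(start, nseg)` of an open
#' chain with `m` segments, `m (m + 1) / 2` cells in total, each carrying the
#' dominant closure type and its frequency.
#'
#' @param chain an [open_chain()].
#' @inheritParams disk_matrix
#' @return a `triangular_matrix` tibble with columns `start`, `nseg`, `knot`,
#'   `freq`; attributes `m`, `failures`.
#' @export
triangular_matrix <- function(chain, dirs = dodecahedron_directions(),
                              table = build_knot_table(), hull_margin = 0.5,
                              view_seed = 1L, tol = 1e-9, budget = 200L,
                              max_nodes = 2e5) {
  stopifnot(inherits(chain, "open_chain"))
  m <- n_segments(chain)
  v <- unclass(chain)
  viewdirs <- view_attempts(NULL, view_seed, 12L)
  dmat <- direction_matrix(dirs)
  w <- dirs$weight
  rows <- list()
  failures <- 0L
  for (s in 0:(m - 1L)) {
    for (k in seq_len(m - s)) {
      r <- .cpp_closure_polys(v[(s + 1):(s + k + 1), , drop = FALSE], dmat,
                              hull_margin, viewdirs, tol, as.integer(budget),
                              max_nodes)
      okk <- r$ok
      failures <- failures + sum(!okk)
      types <- names_from_polys(r$poly[okk], r$bound[okk], table)
      dom <- dominant_of(types, w[okk] / sum(w[okk]), table)
      rows[[length(rows) + 1]] <- list(start = s, nseg = k,
                                       knot = dom$type, freq = dom$frequency)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("triangular_matrix", class(out))
  attr(out, "m") <- m
  attr(out, "failures") <- failures
  out
}

#' Knot core of a disk matrix
#'
#' The shortest subchain(s) whose dominant closure type equals the host's
#' global knot type: the cells of minimal latitude carrying the global type.
#'
#' @param dm a [disk_matrix()].
#' @return a tibble with columns `start`, `nseg`, `freq`.
#' @export
knot_core <- function(dm) {
  global <- attr(dm, "global_type")
  if (global == "0_1") abort("no core: the host is globally unknotted")
  hit <- dm[dm$knot == global, ]
  if (nrow(hit) == 0) abort("global type never dominant in any cell")
  hit <- hit[hit$nseg == min(hit$nseg), c("start", "nseg", "freq")]
  hit
}

# row index of cell (s, k): positional lookup table over start * n + nseg
cell_index <- function(dm) {
  n <- attr(dm, "n")
  pos <- integer(n * n)
  pos[dm$start * n + dm$nseg] <- seq_len(nrow(dm))
  pos
}

#' Trimming paths from an initial scission
#'
#' Removing segment `scission` (0-based) from the host leaves an open chain of
#' `n - 1` segments.  The two returned sequences report the dominant knot type
#' as this chain is shortened one segment at a time from its tail end
#' ("blue") or from its head end ("green"), down to a single segment.  In the
#' disk layout the corresponding cells spiral from the rim towards the centre,
#' with the spiral's handedness set by which end is trimmed.
#'
#' @param dm a [disk_matrix()].
#' @param scission segment index in `[0, n)`.
#' @return a list of two tibbles `blue` and `green`, each with columns `step`,
#'   `start`, `nseg`, `knot`, `freq`.
#' @export
trimming_paths <- function(dm, scission) {
  n <- attr(dm, "n")
  if (scission < 0 || scission >= n) abort("scission must lie in [0, n)")
  s0 <- (scission + 1L) %% n
  ks <- (n - 1L):1L
  pos <- cell_index(dm)
  path <- function(starts) {
    rows <- pos[(starts %% n) * n + ks]
    tibble::tibble(step = seq_along(ks) - 1L, start = dm$start[rows],
                   nseg = dm$nseg[rows], knot = dm$knot[rows],
                   freq = dm$freq[rows])
  }
  list(blue = path(rep(s0, length(ks))),              # trim the far end
       green = path((s0 + (n - 1L) - ks) %% n))       # trim the near end
}

#' Classify scissions by their trimming behaviour
#'
#' For every possible initial scission, the two trimming paths are inspected
#' for the first dominant type differing from the global knot.  A scission is
#' `both_via_K` when both ends first pass through the same nontrivial type K,
#' `both_direct` when both pass straight to the unknot, and `mixed` otherwise.
#' The classes partition the scissions into circular arcs around the host.
#'
#' @param dm a [disk_matrix()].
#' @return a tibble with columns `scission`, `class`, `first_blue`,
#'   `first_green`.
#' @export
scission_classes <- function(dm) {
  global <- attr(dm, "global_type")
  if (global == "0_1") abort("scission classes need a globally knotted host")
  n <- attr(dm, "n")
  first_off <- function(p) {
    i <- match(TRUE, p$knot != global)
    if (is.na(i)) "0_1" else p$knot[i]
  }
  rows <- lapply(0:(n - 1L), function(sc) {
    tp <- trimming_paths(dm, sc)
    fb <- first_off(tp$blue)
    fg <- first_off(tp$green)
    cls <- if (fb == "0_1" && fg == "0_1") "both_direct"
    else if (fb == fg) "both_via_K"
    else "mixed"
    tibble::tibble(scission = sc, class = cls, first_blue = fb, first_green = fg)
  })
  dplyr::bind_rows(rows)
}
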