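#' Subknot report of a disk matrix
#'
#' Collects the knot types formed by the host's subchains: `all_subknots` are
#' the dominant types of at least one cell, `majority_subknots` those whose
#' dominant frequency reaches at least 0.5 in some cell.  Cell counts per type
#' ("area" in the disk) are reported so that callers may threshold rare types;
#' none are filtered here, since complicated subknots of random hosts can be
#' genuine while occupying only a few cells.  For comparisons against
#' predecessor sets the global type itself is excluded from both sets (the
#' unknot is retained), making subknot and predecessor sets commensurable.
#'
#' @param dm a [disk_matrix()].
#' @return a `subknot_report`: list with `global_type`, `all_subknots`,
#'   `majority_subknots`, and a tibble `areas` (`type`, `cells`,
#'   `majority_cells`, `max_freq`).
#' @export
subknot_report <- function(dm) {
  areas <- dm |>
    dplyr::group_by(.data$knot) |>
    dplyr::summarise(cells = dplyr::n(),
                     majority_cells = sum(.data$freq >= 0.5),
                     max_freq = max(.data$freq)) |>
    dplyr::rename(type = "knot") |>
    dplyr::arrange(dplyr::desc(.data$cells))
  structure(list(
    global_type = attr(dm, "global_type"),
    n = attr(dm, "n"),
    all_subknots = sort(unique(dm$knot)),
    majority_subknots = sort(unique(dm$knot[dm$freq >= 0.5])),
    areas = areas
  ), class = "subknot_report")
}

#' @export
print.subknot_report <- function(x, ...) {
  cat("<subknot_report> global", x$global_type, "\n  all:     ",
      paste(x$all_subknots, collapse = ", "), "\n  majority:",
      paste(x$majority_subknots, collapse = ", "), "\n")
  invisible(x)
}

# comparison sets per the convention above: global type excluded, unknot kept
report_sets <- function(report) {
  list(all = setdiff(report$all_subknots, report$global_type),
       majority = setdiff(report$majority_subknots, report$global_type))
}

#' Region graph and subknot generations
#'
#' Groups the cells of a disk matrix into maximal connected regions of equal
#' dominant type.  Cells are adjacent along a latitude (neighbouring
#' longitudes) and across latitudes by the trimming relation: `(s, k)` touches
#' `(s, k-1)` and `(s+1, k-1)` in the brick-wall layout.  Directed edges run
#' from each region to the regions reachable by one trimming step (radially
#' inward); the generation of a knot type is the smallest number of region
#' hops from the global-type rim region, so first-generation subknots are the
#' types whose territory borders the global territory directly.
#'
#' @param dm a [disk_matrix()] with a knotted global type.
#' @return a `region_graph`: list with tibbles `regions` (`region`, `knot`,
#'   `cells`, `min_nseg`, `max_nseg`), `edges` (`from`, `to`), and
#'   `generations` (`type`, `generation`).
#' @export
region_graph <- function(dm) {
  global <- attr(dm, "global_type")
  if (global == "0_1") abort("region graph needs a knotted host")
  n <- attr(dm, "n")
  pos <- cell_index(dm)
  ncell <- nrow(dm)
  parent <- seq_len(ncell)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  at <- function(s, k) pos[(s %% n) * n + k]
  # same-type adjacency unions; cross-type adjacencies recorded for edges
  cross <- list()
  for (i in seq_len(ncell)) {
    s <- dm$start[i]; k <- dm$nseg[i]
    j <- at(s + 1L, k)   # same latitude, next longitude
    if (j > 0 && dm$knot[i] == dm$knot[j]) union_(i, j)
    for (s2 in c(s, s + 1L)) {
      if (k > 1L) {
        j <- at(s2, k - 1L)
        if (dm$knot[i] == dm$knot[j]) union_(i, j)
        else cross[[length(cross) + 1]] <- c(i, j)
      }
    }
  }
  root <- vapply(seq_len(ncell), find, integer(1))
  region_id <- match(root, unique(root))
  regions <- tibble::tibble(cell = seq_len(ncell), region = region_id,
                            knot = dm$knot, nseg = dm$nseg) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(knot = .data$knot[1], cells = dplyr::n(),
                     min_nseg = min(.data$nseg), max_nseg = max(.data$nseg))
  edges <- unique(do.call(rbind, lapply(cross, function(e) {
    c(from = region_id[e[1]], to = region_id[e[2]])
  })))
  edges <- tibble::as_tibble(if (is.null(edges)) {
    list(from = integer(0), to = integer(0))
  } else as.data.frame(edges))
  # rim region(s) of the global type: those containing global cells of
  # maximal latitude
  gl <- regions$region[regions$knot == global]
  if (length(gl) == 0) abort("global type never dominant in any cell")
  top <- max(regions$max_nseg[regions$region %in% gl])
  start_regions <- regions$region[regions$knot == global & regions$max_nseg == top]
  # BFS over directed edges
  nreg <- nrow(regions)
  dist <- rep(NA_integer_, nreg)
  dist[start_regions] <- 0L
  frontier <- start_regions
  while (length(frontier) > 0) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0) break
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  gens <- tibble::tibble(region = regions$region, knot = regions$knot,
                         hops = dist) |>
    dplyr::filter(!is.na(.data$hops)) |>
    dplyr::group_by(type = .data$knot) |>
    dplyr::summarise(generation = min(.data$hops))
  structure(list(regions = regions, edges = edges, generations = gens,
                 global_type = global),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat("<region_graph>", nrow(x$regions), "regions,", nrow(x$edges), "edges\n")
  print(x$generations)
  invisible(x)
}

#' Extract a subknot as a standalone closed polygon
#'
#' Implements the distributive search for higher-generation subknots: a
#' subchain whose cell carries a nontrivial dominant type K is closed in a
#' direction that actually realizes K, but the rays are cut as soon as they
#' leave the subchain's convex hull before being joined, producing a compact
#' closed polygon of type K that can itself be dissected with
#' [disk_matrix()].
#'
#' @param polygon the host [polygon3()].
#' @param cell a list or one-row tibble with `start` and `nseg`.
#' @param dirs a [direction_set()] of candidate closure directions.
#' @param table a [build_knot_table()].
#' @param type the expected type; defaults to the dominant type of the cell's
#'   spectrum, recomputed here.
#' @param ... passed to [classify()].
#' @return a [polygon3()] classifying as `type`, with attribute `direction`.
#' @export
extract_subknot <- function(polygon, cell, dirs = dodecahedron_directions(),
                            table = build_knot_table(), type = NULL, ...) {
  chain <- make_subchain(polygon, cell$start, cell$nseg)
  spec <- closure_spectrum(chain, dirs, table = table)
  if (is.null(type)) type <- dominant(spec)$type
  if (type == "0_1") abort("refusing to extract a trivial subknot")
  v <- unclass(chain)
  m <- nrow(v)
  dmat <- direction_matrix(dirs)
  diam <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  for (i in order(-dirs$weight)) {
    d <- dmat[i, ]
    proj <- as.numeric(v %*% d)
    # each ray cut just outside the hull: beyond the extreme vertex along d
    la <- max(proj) - proj[1] + 0.05 * diam
    lb <- max(proj) - proj[m] + 0.05 * diam
    cand <- tryCatch(polygon3(rbind(v, v[m, ] + lb * d, v[1, ] + la * d)),
                     error = function(e) NULL)
    if (is.null(cand)) next
    got <- tryCatch(as.character(classify(cand, table = table, ...)),
                    error = function(e) NA_character_)
    if (identical(got, type)) {
      attr(cand, "direction") <- d
      return(cand)
    }
  }
  abort(paste0("no closure direction realizes type ", type, " for this cell"))
}

#' Compare a subknot report against a reference set
#'
#' Produces the four containment checks used to tabulate agreement between
#' subknot sets and predecessor sets: whether all subknots belong to the
#' reference, whether the whole reference is realized among the subknots,
#' whether the majority subknots belong to the reference, and whether a
#' designated first-generation reference subset is realized among the
#' subknots.  The global type is excluded from the subknot sets (see
#' [subknot_report()]); the reference is expected to exclude it too and to
#' contain the unknot.
#'
#' @param report a [subknot_report()].
#' @param reference character vector of reference types (e.g. all
#'   predecessors).
#' @param first_generation optional character vector (e.g. first-generation
#'   predecessors).
#' @return a one-row tibble with logical columns `subknots_in_reference`,
#'   `reference_in_subknots`, `majority_in_reference`,
#'   `first_generation_in_subknots`.
#' @export
compare_to_reference <- function(report, reference, first_generation = NULL) {
  s <- report_sets(report)
  tibble::tibble(
    subknots_in_reference = all(s$all %in% reference),
    reference_in_subknots = all(reference %in% s$all),
    majority_in_reference = all(s$majority %in% reference),
    first_generation_in_subknots =
      is.null(first_generation) || all(first_generation %in% s$all)
  )
}

#' Test whether given types occur as subknots of a host
#'
#' Evaluates disk-matrix cells latitude by latitude -- the cheap innermost
#' latitudes first, then from the rim inward -- and stops as soon as every
#' requested type has been seen as a dominant cell type.  This is the
#' economical form of the containment question "does every predecessor of the
#' global type occur among the subknots?", which does not need the full
#' matrix when the answer is yes.
#'
#' @param polygon a [polygon3()] host.
#' @param types character vector of knot type names to find.
#' @inheritParams disk_matrix
#' @return a list with `contains` (logical), `missing`, `seen`, and
#'   `cells_evaluated`.
#' @export
contains_subknots <- function(polygon, types, dirs = dodecahedron_directions(),
                              table = build_knot_table(), hull_margin = 0.5,
                              view_seed = 1L, tol = 1e-9, budget = 200L,
                              max_nodes = 2e5) {
  stopifnot(inherits(polygon, "polygon3"))
  n <- n_segments(polygon)
  v <- unclass(polygon)
  viewdirs <- view_attempts(NULL, view_seed, 12L)
  dmat <- direction_matrix(dirs)
  w <- dirs$weight
  want <- unique(types)
  seen <- character(0)
  evaluated <- 0L
  # bottom-up: random knots are localized, so predecessor territories sit at
  # low and middle latitudes where closures are cheapest.  Latitudes are
  # visited with stride 3 first: territories are several latitudes thick, so
  # this usually finds every type at a third of the cost; the interleaved
  # fallback passes restore completeness when a type is genuinely missing or
  # its territory is thin.
  lat_order <- c(seq(1L, n - 1L, by = 3L), seq(2L, n - 1L, by = 3L),
                 seq(3L, n - 1L, by = 3L))
  for (k in lat_order) {
    for (s in 0:(n - 1L)) {
      idx <- (s + 0:k) %% n + 1L
      r <- .cpp_closure_polys(v[idx, , drop = FALSE], dmat, hull_margin,
                              viewdirs, tol, as.integer(budget), max_nodes)
      okk <- r$ok
      if (!any(okk)) next
      tys <- names_from_polys(r$poly[okk], r$bound[okk], table)
      dom <- dominant_of(tys, w[okk] / sum(w[okk]), table)
      evaluated <- evaluated + 1L
      if (!dom$type %in% seen) {
        seen <- c(seen, dom$type)
        if (all(want %in% seen))
          return(list(contains = TRUE, missing = character(0), seen = sort(seen),
                      cells_evaluated = evaluated))
      }
    }
  }
  list(contains = FALSE, missing = setdiff(want, seen), seen = sort(seen),
       cells_evaluated = evaluated)
}
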