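#' Knot identification table
#'
#' Builds the lookup table used to turn HOMFLYPT polynomials into named chiral
#' knot types.  Every prime knot up to `max_crossings` crossings is realized
#' from its embedded DT code, its polynomial computed by skein recursion, and
#' both chiralities entered (the mirror polynomial under `l -> 1/l`; knots
#' whose polynomial is palindromic in this sense are stored once, as
#' amphichiral).  Composite knots are added as `#`-joined sorted factor names
#' for every multiset of primes with total crossing number at most
#' `max_crossings`, with polynomial equal to the product of the factors'.
#'
#' Distinct knot types sharing a polynomial (rare, but present below 11
#' crossings) are stored as candidate lists; [classify()] disambiguates them
#' with the simplified diagram's crossing count.
#'
#' Chirality convention: the diagram realized from the embedded DT code with
#' the maximal-writhe planar embedding carries the plain name (`3_1`), its
#' mirror the `-` name (`-3_1`).  This is internally consistent across the
#' whole table but involves an arbitrary global choice per chiral knot.
#'
#' @param max_crossings table depth, 3 to 10.
#' @param composites include composite knots (default TRUE).
#' @return an object of class `knot_table`.
#' @export
build_knot_table <- function(max_crossings = 10L, composites = TRUE) {
  if (max_crossings > 10) abort("embedded DT codes stop at 10 crossings")
  key <- paste0("kt", max_crossings, composites)
  if (!is.null(the$tables[[key]])) return(the$tables[[key]])

  dtab <- read_dt_table()
  dtab <- dtab[dtab$crossings <= max_crossings, ]
  entries <- list()
  diagrams <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dtab))) {
    nm <- dtab$name[i]
    d <- diagram_from_dt(dtab$dt[[i]])
    p <- .cpp_homfly(unclass(d), 2e5)
    pm <- poly_mirror_str(p)
    assign(nm, d, envir = diagrams)
    amphi <- identical(p, pm)
    entries[[length(entries) + 1]] <- tibble::tibble(
      name = nm, poly = p, crossings = dtab$crossings[i],
      alternating = dtab$alternating[i], composite = FALSE, amphichiral = amphi)
    if (!amphi)
      entries[[length(entries) + 1]] <- tibble::tibble(
        name = paste0("-", nm), poly = pm, crossings = dtab$crossings[i],
        alternating = dtab$alternating[i], composite = FALSE, amphichiral = FALSE)
  }
  primes <- dplyr::bind_rows(entries)

  comp <- NULL
  if (composites) {
    comp <- build_composites(primes, max_crossings)
  }
  all_entries <- dplyr::bind_rows(primes, comp)

  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(all_entries))) {
    p <- all_entries$poly[i]
    assign(p, c(lookup[[p]], all_entries$name[i]), envir = lookup)
  }
  collisions <- all_entries$poly[duplicated(all_entries$poly)]

  kt <- structure(list(
    entries = all_entries,
    lookup = lookup,
    diagrams = diagrams,
    max_crossings = as.integer(max_crossings),
    collisions = unique(collisions),
    cache = new.env(parent = emptyenv())   # predecessor sets, name maps
  ), class = "knot_table")
  the$tables[[key]] <- kt
  kt
}

build_composites <- function(primes, max_crossings) {
  base <- primes[!primes$composite, ]
  rows <- list()
  # multisets of signed prime names with total crossing number <= max
  grow <- function(factors, total, min_idx) {
    if (length(factors) >= 1 && length(factors) >= 2) {
      nm <- paste(sort_factors(factors, base), collapse = "#")
      polys <- base$poly[match(factors, base$name)]
      rows[[length(rows) + 1]] <<- tibble::tibble(
        name = nm, poly = .cpp_poly_product(polys),
        crossings = total, composite = TRUE,
        alternating = all(base$alternating[match(factors, base$name)]),
        amphichiral = NA)
    }
    for (j in seq(min_idx, nrow(base))) {
      cn <- base$crossings[j]
      if (total + cn <= max_crossings)
        grow(c(factors, base$name[j]), total + cn, j)
    }
  }
  grow(character(0), 0L, 1L)
  out <- dplyr::bind_rows(rows)
  out <- out[!duplicated(out$name), ]
  # amphichiral iff the mirrored factor multiset is the same composite
  out$amphichiral <- vapply(out$name, function(nm) {
    identical(mirror_composite_name(nm, base), nm)
  }, logical(1))
  out
}

sort_factors <- function(factors, base) {
  cn <- base$crossings[match(factors, base$name)]
  factors[order(cn, factors)]
}

mirror_composite_name <- function(nm, base) {
  f <- strsplit(nm, "#", fixed = TRUE)[[1]]
  mf <- vapply(f, function(x) mirror_prime_name(x, base), character(1))
  paste(sort_factors(mf, base), collapse = "#")
}

mirror_prime_name <- function(x, entries) {
  bare <- sub("^-", "", x)
  amphi <- isTRUE(entries$amphichiral[match(bare, entries$name)])
  if (amphi) return(bare)
  if (startsWith(x, "-")) bare else paste0("-", x)
}

#' @export
print.knot_table <- function(x, ...) {
  cat("<knot_table> up to", x$max_crossings, "crossings:",
      sum(!x$entries$composite), "prime entries (chiralities counted),",
      sum(x$entries$composite), "composites,",
      length(x$collisions), "polynomial collisions\n")
  invisible(x)
}

#' Knot type names
#'
#' Helpers over the naming scheme: `0_1` is the unknot, `3_1` / `-3_1` a
#' chiral pair, `3_1#-3_1` a composite of sorted factors, `unknown:<hash>` a
#' type outside the table identified only by its polynomial hash.
#'
#' @param names character vector of knot type names.
#' @param table a [build_knot_table()] result (used for amphichirality when
#'   mirroring names).
#' @return `knot_crossing_number()` an integer vector (NA for unknown types);
#'   `mirror_name()` the names of the mirror types.
#' @export
knot_crossing_number <- function(names) {
  vapply(names, function(nm) {
    if (is.na(nm)) return(NA_integer_)
    if (nm == "0_1") return(0L)
    if (startsWith(nm, "unknown:")) return(NA_integer_)
    f <- strsplit(nm, "#", fixed = TRUE)[[1]]
    sum(vapply(f, function(x) as.integer(sub("_.*", "", sub("^-", "", x))),
               integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname knot_crossing_number
#' @export
mirror_name <- function(names, table = build_knot_table()) {
  entries <- table$entries[!table$entries$composite, ]
  vapply(names, function(nm) {
    if (nm == "0_1" || startsWith(nm, "unknown:")) return(nm)
    f <- strsplit(nm, "#", fixed = TRUE)[[1]]
    mf <- vapply(f, function(x) mirror_prime_name(x, entries), character(1))
    paste(sort_factors(mf, entries), collapse = "#")
  }, character(1), USE.NAMES = FALSE)
}

base_name <- function(names) {
  vapply(strsplit(names, "#", fixed = TRUE),
         function(f) paste(sub("^-", "", f), collapse = "#"), character(1))
}

# minimal diagram of a named type: realized prime diagrams (mirrored for "-"
# names), plumbed connected sums for composites
minimal_diagram <- function(name, table) {
  if (name == "0_1") return(crossing_diagram(list(), integer(0)))
  f <- strsplit(name, "#", fixed = TRUE)[[1]]
  ds <- lapply(f, function(x) {
    bare <- sub("^-", "", x)
    d <- get0(bare, envir = table$diagrams)
    if (is.null(d)) abort(paste0("no minimal diagram for ", x))
    if (startsWith(x, "-")) mirror_diagram(d) else d
  })
  Reduce(connect_sum_diagram, ds)
}

#' Identify the knot type of a diagram or polygon
#'
#' The identification pipeline of the package: project (polygons only),
#' simplify, compute the HOMFLYPT polynomial, and look the polynomial up in
#' the knot table.  When several table entries share the polynomial, any
#' candidate whose minimal crossing number exceeds the simplified diagram's
#' crossing count is discarded; if more than one candidate survives, the one
#' with the smallest crossing number is returned flagged ambiguous.  A
#' polynomial absent from the table yields `unknown:<hash>`.
#'
#' @param x a [polygon3()] or [crossing_diagram()].
#' @param table a [build_knot_table()].
#' @param view_seed seed for the default projection direction.
#' @param budget Reidemeister III search budget.
#' @param max_nodes skein recursion cap.
#' @param ... passed to methods.
#' @return a length-1 character knot name with attributes `poly`, `bound`
#'   (simplified crossing count) and `ambiguous`.
#' @export
classify <- function(x, ...) UseMethod("classify")

#' @rdname classify
#' @export
classify.polygon3 <- function(x, table = build_knot_table(), view_seed = 1L,
                              tol = 1e-9, budget = 1000L, max_nodes = 2e5, ...) {
  dirs <- view_attempts(NULL, view_seed, 12L)
  r <- .cpp_polygon_poly(unclass(x), dirs, tol, as.integer(budget), max_nodes)
  if (!isTRUE(r$ok)) abort(paste0("classification failed: ", r$msg))
  name_from_poly(r$poly, r$bound, table)
}

#' @rdname classify
#' @param tol projection genericity tolerance.
#' @export
classify.crossing_diagram <- function(x, table = build_knot_table(),
                                      budget = 1000L, max_nodes = 2e5, ...) {
  s <- .cpp_simplify(unclass(x), as.integer(budget))
  p <- .cpp_homfly(s, max_nodes)
  bound <- length(s$sign)
  name_from_poly(p, bound, table)
}

name_from_poly <- function(poly, bound, table) {
  cand <- table$lookup[[poly]]
  if (identical(poly, HOMFLY_UNKNOT)) cand <- unique(c("0_1", cand))
  if (is.null(cand)) {
    out <- paste0("unknown:", fnv1a32(poly))
    attr(out, "poly") <- poly
    attr(out, "bound") <- bound
    attr(out, "ambiguous") <- FALSE
    return(out)
  }
  cn <- knot_crossing_number(cand)
  keep <- cand[cn <= bound]
  if (length(keep) == 0) keep <- cand
  cnk <- knot_crossing_number(keep)
  ord <- order(cnk, keep)
  out <- keep[ord[1]]
  attr(out, "poly") <- poly
  attr(out, "bound") <- bound
  attr(out, "ambiguous") <- length(keep) > 1
  out
}

# bare-string fast path used by the spectrum/matrix loops; memoizes the
# poly -> name resolution per table in table$cache
names_from_polys <- function(polys, bounds, table) {
  cache <- table$cache
  out <- character(length(polys))
  for (k in seq_along(polys)) {
    p <- polys[k]
    hit <- get0(p, envir = cache)
    if (!is.null(hit)) { out[k] <- hit; next }
    nm <- as.character(name_from_poly(p, bounds[k], table))
    # cache only when the crossing bound cannot change the answer
    cand <- table$lookup[[p]]
    if (is.null(cand) || length(cand) == 1) assign(p, nm, envir = cache)
    out[k] <- nm
  }
  out
}
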