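#' Predecessor knots by single crossing changes
#'
#' The first-generation predecessors of a knot are the types obtained by
#' switching one crossing, in turn, of a minimal crossing diagram.  For
#' alternating knots this set is independent of which minimal diagram is used
#' (all are related by flypes), which is why the analysis is restricted to
#' alternating types; requesting a non-alternating knot raises an error.  The
#' per-crossing outcome multiset is returned alongside the set, since the
#' frequency with which each predecessor arises is informative.
#'
#' Minimal diagrams come from the embedded DT table (mirrored for `-` names);
#' composite knots use the plumbed connected sum of their factors' minimal
#' diagrams.
#'
#' @param knot a knot name, e.g. `"7_5"` or `"-7_7"` or `"3_1#-3_1"`.
#' @param table a [build_knot_table()].
#' @return a list with `set` (sorted distinct outcome types) and `outcomes`
#'   (one type per crossing of the minimal diagram).
#' @export
first_generation <- function(knot, table = build_knot_table()) {
  check_alternating(knot, table)
  fg_core(knot, table)
}

# uncached core + per-table memo; no alternating gate (used by the closure,
# which flags non-alternating types itself)
fg_core <- function(knot, table) {
  key <- paste0("fg.", knot)
  hit <- get0(key, envir = table$cache)
  if (!is.null(hit)) return(hit)
  d <- minimal_diagram(knot, table)
  ids <- sort(unique(d$comps[[1]][1, ]))
  outcomes <- vapply(ids, function(id) {
    as.character(classify(crossing_change(d, id), table = table))
  }, character(1))
  res <- list(set = sort(unique(outcomes)), outcomes = outcomes)
  assign(key, res, envir = table$cache)
  res
}

check_alternating <- function(knot, table) {
  if (knot == "0_1") abort("the unknot has no crossings to change")
  f <- base_name(strsplit(knot, "#", fixed = TRUE)[[1]])
  alt <- table$entries$alternating[match(f, table$entries$name)]
  if (anyNA(alt)) abort(paste0("unknown knot type: ", knot))
  if (!all(alt))
    abort(paste0("predecessors are undefined for non-alternating knots (",
                 knot, "): different minimal diagrams give different sets"))
  invisible(TRUE)
}

#' Generational closure of the predecessor relation
#'
#' Breadth-first expansion of [first_generation()]: generation g+1 collects
#' the types arising from single crossing changes in minimal diagrams of the
#' generation-g types, each type labelled with the first generation at which
#' it appears.  The unknot terminates every chain.  The closure is `defined`
#' only if every reached type is alternating (or the unknot, or a composite
#' of alternating primes); reaching a non-alternating or unidentifiable type
#' clears the flag, and such types are not expanded further since their own
#' predecessor sets would be diagram-dependent.
#'
#' @param knot an alternating knot name (chirality-resolved).
#' @param max_gen generation cap.
#' @param table a [build_knot_table()].
#' @return a `predecessor_set`: list with `knot`, `generations` (list of
#'   character vectors), `all` (every type reached), `defined` (logical),
#'   `outcomes_gen1`, and `undefined_via` (the offending types, if any).
#' @export
generational_closure <- function(knot, max_gen = 20L,
                                 table = build_knot_table()) {
  check_alternating(knot, table)
  seen <- knot
  gens <- list()
  defined <- TRUE
  undefined_via <- character(0)
  frontier <- knot
  g <- 0L
  gen1_outcomes <- NULL
  while (length(frontier) > 0 && g < max_gen) {
    g <- g + 1L
    nxt <- character(0)
    for (k in frontier) {
      fg <- fg_core(k, table)
      if (g == 1L) gen1_outcomes <- fg$outcomes
      nxt <- union(nxt, fg$set)
    }
    nxt <- setdiff(nxt, seen)
    if (length(nxt) == 0) break
    gens[[g]] <- sort(nxt)
    seen <- c(seen, nxt)
    expandable <- vapply(nxt, function(t) {
      if (t == "0_1") return(FALSE)
      if (startsWith(t, "unknown:")) {
        defined <<- FALSE
        undefined_via <<- union(undefined_via, t)
        return(FALSE)
      }
      f <- base_name(strsplit(t, "#", fixed = TRUE)[[1]])
      alt <- table$entries$alternating[match(f, table$entries$name)]
      if (anyNA(alt) || !all(alt)) {
        defined <<- FALSE
        undefined_via <<- union(undefined_via, t)
        return(FALSE)
      }
      TRUE
    }, logical(1))
    frontier <- nxt[expandable]
  }
  structure(list(knot = knot, generations = gens,
                 all = sort(setdiff(seen, knot)), defined = defined,
                 outcomes_gen1 = gen1_outcomes,
                 undefined_via = undefined_via),
            class = "predecessor_set")
}

#' @export
print.predecessor_set <- function(x, ...) {
  cat("<predecessor_set>", x$knot,
      if (x$defined) "(defined)" else "(undefined)", "\n")
  for (g in seq_along(x$generations))
    cat("  gen", g, ":", paste(x$generations[[g]], collapse = ", "), "\n")
  invisible(x)
}

#' Census of alternating knots with defined predecessor sets
#'
#' Counts, among the alternating prime knots of a given crossing number, those
#' whose full generational predecessor closure stays within the alternating
#' world (every reached type alternating, unknot, or composite of alternating
#' primes).  Chirality does not affect definedness, so each type is examined
#' once through its representative name.
#'
#' @param crossing_number 3 to 10.
#' @param table a [build_knot_table()]; must cover `crossing_number`.
#' @return a tibble with columns `name`, `defined`, `undefined_via`; the
#'   number of defined types is `sum(.$defined)`.
#' @export
defined_census <- function(crossing_number, table = build_knot_table()) {
  stopifnot(crossing_number >= 3, crossing_number <= table$max_crossings)
  e <- table$entries
  names <- e$name[!e$composite & e$alternating & !startsWith(e$name, "-") &
                    e$crossings == crossing_number]
  rows <- lapply(names, function(nm) {
    pc <- generational_closure(nm, table = table)
    tibble::tibble(name = nm, defined = pc$defined,
                   undefined_via = paste(pc$undefined_via, collapse = " "))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "count_defined") <- sum(out$defined)
  out
}
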