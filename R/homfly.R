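#' HOMFLYPT polynomial of a link diagram
#'
#' Computes the two-variable HOMFLYPT polynomial by skein recursion in the
#' (l, m) convention
#' \deqn{l P(L_+) + l^{-1} P(L_-) + m P(L_0) = 0,}
#' with the unknot normalized to 1.  At each step the first crossing met as an
#' underpass along the traversal is switched and smoothed (the descending
#' diagram heuristic); descending diagrams are unlinks with
#' \eqn{P = (-(l + l^{-1})/m)^{k-1}}.  Subdiagrams are reduced by Reidemeister
#' I/II before being memoized on their canonical Gauss code, which keeps the
#' recursion tree far below its worst case.  In this convention the mirror
#' image of a link corresponds to the substitution \eqn{l \to l^{-1}}, and the
#' polynomial of a connected sum is the product of the factors'.
#'
#' @param diagram a [crossing_diagram()].
#' @param max_nodes safety cap on visited skein-tree nodes; exceeding it
#'   raises an error naming the diagram size.
#' @return an object of class `homfly`: a tibble with columns `l`, `m`
#'   (exponents) and `coef`, plus a canonical string encoding in
#'   `attr(, "poly")`.
#' @export
homfly <- function(diagram, max_nodes = 2e5) {
  stopifnot(inherits(diagram, "crossing_diagram"))
  new_homfly(.cpp_homfly(unclass(diagram), max_nodes))
}

new_homfly <- function(poly_string) {
  tb <- parse_poly(poly_string)
  attr(tb, "poly") <- poly_string
  class(tb) <- c("homfly", class(tb))
  tb
}

parse_poly <- function(s) {
  if (identical(s, "0") || !nzchar(s))
    return(tibble::tibble(l = integer(), m = integer(), coef = numeric()))
  terms <- strsplit(s, "|", fixed = TRUE)[[1]]
  parts <- do.call(rbind, strsplit(terms, "[,:]"))
  tibble::tibble(l = as.integer(parts[, 1]), m = as.integer(parts[, 2]),
                 coef = as.numeric(parts[, 3]))
}

#' @export
print.homfly <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<homfly> 0\n")
    return(invisible(x))
  }
  term <- function(l, m, co) {
    s <- if (co >= 0) "+ " else "- "
    v <- abs(co)
    paste0(s, v,
           if (l != 0) paste0(" l^", l) else "",
           if (m != 0) paste0(" m^", m) else "")
  }
  cat("<homfly>", paste(mapply(term, x$l, x$m, x$coef), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.character.homfly <- function(x, ...) attr(x, "poly")

#' @rdname homfly
#' @param x a `homfly` object.
#' @export
homfly_mirror <- function(x) new_homfly(.cpp_poly_mirror(attr(x, "poly")))

#' @rdname homfly
#' @param ... `homfly` objects to multiply (connected sums).
#' @export
homfly_product <- function(...) {
  polys <- vapply(list(...), function(x) attr(x, "poly"), character(1))
  new_homfly(.cpp_poly_product(polys))
}

#' @rdname homfly
#' @details `homfly_det()` evaluates the knot determinant
#'   \eqn{|\Delta_K(-1)|} from the polynomial (at \eqn{l = -i, m = 2}), a
#'   cheap classical invariant used to validate table entries.
#' @export
homfly_det <- function(x) {
  v <- .cpp_poly_eval(attr(x, "poly"), 0, -1, 2, 0)
  round(sqrt(v[1]^2 + v[2]^2))
}

poly_mirror_str <- function(s) .cpp_poly_mirror(s)

HOMFLY_UNKNOT <- "0,0:1"
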