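#' Tidiers for package result objects
#'
#' broom-style accessors: `tidy()` returns the per-element breakdown of a
#' result as a tibble, `glance()` a one-row summary.
#'
#' @param x a package result object.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.subknot_report <- function(x, ...) {
  dplyr::mutate(x$areas,
                is_global = .data$type == x$global_type,
                majority = .data$type %in% x$majority_subknots)
}

#' @rdname tidiers
#' @export
glance.subknot_report <- function(x, ...) {
  tibble::tibble(global_type = x$global_type, n = x$n,
                 n_subknots = length(x$all_subknots),
                 n_majority = length(x$majority_subknots))
}

#' @rdname tidiers
#' @export
tidy.predecessor_set <- function(x, ...) {
  if (length(x$generations) == 0)
    return(tibble::tibble(generation = integer(), type = character()))
  dplyr::bind_rows(lapply(seq_along(x$generations), function(g) {
    tibble::tibble(generation = g, type = x$generations[[g]])
  }))
}

#' @rdname tidiers
#' @export
glance.predecessor_set <- function(x, ...) {
  tibble::tibble(knot = x$knot, defined = x$defined,
                 n_generations = length(x$generations),
                 n_types = length(x$all))
}

#' @rdname tidiers
#' @export
glance.disk_matrix <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), global_type = attr(x, "global_type"),
                 n_cells = nrow(x), n_types = length(unique(x$knot)),
                 failures = attr(x, "failures"))
}

#' @rdname tidiers
#' @export
tidy.region_graph <- function(x, ...) x$generations

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
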