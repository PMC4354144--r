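#' Plot disk and triangular matrices
#'
#' `autoplot.disk_matrix()` renders the polar layout: each cell is a brick at
#' angular position `longitude` (subchain midpoint) and radius `nseg`
#' (subchain length), filled by dominant knot type with opacity mapped to the
#' dominant frequency, so borders between knot territories fade exactly where
#' the closure spectrum is contested.  Bricks crossing the angular seam are
#' split in two.  `autoplot.triangular_matrix()` draws the linear-chain
#' analogue as a right triangle.
#'
#' @param object a `disk_matrix` or `triangular_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.disk_matrix <- function(object, ...) {
  n <- attr(object, "n")
  df <- tibble::tibble(lon0 = object$longitude - 0.5,
                       lon1 = object$longitude + 0.5,
                       r0 = object$nseg - 0.5, r1 = object$nseg + 0.5,
                       knot = object$knot, freq = object$freq)
  seam <- df$lon1 > n
  if (any(seam)) {
    wrapped <- df[seam, ]
    df$lon1[seam] <- n
    wrapped$lon0 <- 0
    wrapped$lon1 <- wrapped$lon1 - n + wrapped$lon0
    df <- dplyr::bind_rows(df, wrapped)
  }
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lon0, xmax = .data$lon1,
                                    ymin = .data$r0, ymax = .data$r1,
                                    fill = .data$knot, alpha = .data$freq)) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(0, n)) +
    ggplot2::scale_alpha(range = c(0.15, 1), limits = c(0, 1)) +
    ggplot2::labs(x = "subchain midpoint (longitude)",
                  y = "subchain length (latitude)",
                  fill = "dominant type", alpha = "frequency",
                  title = paste0("disk matrix, global type ",
                                 attr(object, "global_type"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.disk_matrix
#' @export
autoplot.triangular_matrix <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_tile(ggplot2::aes(x = .data$start + .data$nseg / 2,
                                    y = .data$nseg, fill = .data$knot,
                                    alpha = .data$freq), width = 1, height = 1) +
    ggplot2::scale_alpha(range = c(0.15, 1), limits = c(0, 1)) +
    ggplot2::labs(x = "subchain midpoint", y = "subchain length",
                  fill = "dominant type", alpha = "frequency") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.disk_matrix
#' @param x the object to plot.
#' @export
plot.disk_matrix <- function(x, ...) print(autoplot.disk_matrix(x, ...))

#' @rdname autoplot.disk_matrix
#' @export
plot.triangular_matrix <- function(x, ...) print(autoplot.triangular_matrix(x, ...))

#' Plot a closure spectrum
#'
#' @param object a `knot_spectrum`.
#' @param ... unused.
#' @export
autoplot.knot_spectrum <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_col(ggplot2::aes(x = stats::reorder(.data$type, -.data$weight),
                                   y = .data$weight)) +
    ggplot2::labs(x = "knot type", y = "closure weight") +
    ggplot2::theme_minimal()
}
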