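#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sketch layout
#'
#' One row per node: final coordinates, whether the node was anchored to
#' the sketch, and the node's anchor coordinates when available.
#'
#' @param x A `sketch_layout`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `x`, `y`, `anchored`,
#'   `anchor_x`, `anchor_y`.
#' @export
tidy.sketch_layout <- function(x, ...) {
  m <- match(x$positions$node, x$anchors$node)
  out <- x$positions
  out$anchored <- !is.na(m)
  out$anchor_x <- x$anchors$x[m]
  out$anchor_y <- x$anchors$y[m]
  out
}

#' @rdname tidy.sketch_layout
#' @export
tidy.sketch_pipeline <- function(x, ...) tidy(x$layout, ...)

#' One-row summary of a sketch layout
#'
#' @param x A `sketch_layout`.
#' @param ... Unused.
#' @return A tibble with node/edge/constraint counts, the fraction of
#'   satisfied constraints, the worst residual, and the fidelity score.
#' @export
glance.sketch_layout <- function(x, ...) {
  tibble::tibble(
    nodes = nrow(x$positions),
    edges = igraph::ecount(x$graph),
    relative_constraints = nrow(x$constraints$relatives),
    alignment_groups = nrow(x$constraints$alignments),
    prop_satisfied = if (nrow(x$report)) mean(x$report$satisfied) else NA_real_,
    max_residual = if (nrow(x$report)) max(x$report$residual) else NA_real_,
    fidelity = x$fidelity,
    refined = x$refined
  )
}

#' @rdname glance.sketch_layout
#' @export
glance.sketch_pipeline <- function(x, ...) {
  dplyr::mutate(glance(x$layout),
                chain_segments = nrow(x$chain),
                chain_closed = chain_closed(x$chain),
                mapping_kind = attr(x$mapping, "kind"),
                .before = 1)
}

#' Plot a sketch layout
#'
#' Nodes and edges at their final positions, drawn in image coordinates
#' (y axis reversed so the plot matches the sketch orientation). Anchored
#' nodes are filled; free (degree-one or unmapped) nodes are hollow.
#'
#' @param object A `sketch_layout` or `sketch_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sketch_layout <- function(object, ...) {
  pos <- tidy(object)
  em <- igraph::as_edgelist(object$graph)
  ed <- tibble::tibble(
    x = pos$x[match(em[, 1], pos$node)],
    y = pos$y[match(em[, 1], pos$node)],
    xend = pos$x[match(em[, 2], pos$node)],
    yend = pos$y[match(em[, 2], pos$node)]
  )
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      colour = "grey60", linewidth = 0.4
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$anchored), size = 2,
                        colour = "#2166ac") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname autoplot.sketch_layout
#' @export
autoplot.sketch_pipeline <- function(object, ...) {
  p <- autoplot(object$layout, ...)
  ch <- tibble::as_tibble(object$chain)
  p + ggplot2::geom_segment(
    data = ch,
    ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
    colour = "#b2182b", linetype = "dashed", linewidth = 0.3,
    inherit.aes = FALSE
  )
}

#' Plot a segment chain
#'
#' @param object A `sketch_chain`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sketch_chain <- function(object, ...) {
  ch <- tibble::as_tibble(object)
  ggplot2::ggplot(ch) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "#b2182b"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}
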