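#' Plot a compatibility graph as a weight heatmap
#'
#' @param object A `kex_graph`.
#' @param ... Unused.
#' @return A ggplot: donor pair on the y axis, recipient pair on the x
#'   axis, tile fill = edge weight (white where no edge exists).
#' @importFrom ggplot2 autoplot
#' @method autoplot kex_graph
#' @export
autoplot.kex_graph <- function(object, ...) {
  df <- tidyr::expand_grid(donor_pair = object$pair_ids,
                           recipient_pair = object$pair_ids) |>
    dplyr::mutate(weight = as.vector(t(object$weights)))
  ggplot2::ggplot(df, ggplot2::aes(.data$recipient_pair, .data$donor_pair,
                                   fill = .data$weight)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$weight), size = 3) +
    ggplot2::scale_y_reverse(breaks = object$pair_ids) +
    ggplot2::scale_x_continuous(breaks = object$pair_ids,
                                position = "top") +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(x = "recipient pair", y = "donor pair",
                  fill = "edge weight",
                  title = "Donor-recipient compatibility weights") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Plot the selected exchange cycles
#'
#' Pairs are laid out on a circle; arrows show the donor-to-recipient
#' transplants of the selected vertex-disjoint cycles.
#'
#' @param object A `kex_solution`.
#' @param n_pairs Total number of pairs in the cohort (defaults to the
#'   largest vertex id in the solution plus one).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kex_solution
#' @export
autoplot.kex_solution <- function(object, n_pairs = NULL, ...) {
  verts <- unlist(object$cycles$vertices)
  if (is.null(n_pairs)) n_pairs <- if (length(verts)) max(verts) + 1 else 2
  theta <- 2 * pi * (0:(n_pairs - 1)) / n_pairs
  layout <- tibble::tibble(pair = 0:(n_pairs - 1),
                           x = cos(theta), y = sin(theta))
  edges <- assignment_table(object) |>
    dplyr::left_join(layout, by = c(donor_pair = "pair")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c(recipient_pair = "pair"))
  p <- ggplot2::ggplot(layout, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 8, colour = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = .data$pair)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Exchange solution: %d cycle(s), total weight %d",
                                  nrow(object$cycles), object$total_weight))
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.25, "cm")),
      colour = "#b2182b", linewidth = 0.7, inherit.aes = FALSE
    )
  }
  p
}
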