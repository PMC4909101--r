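#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binding result
#'
#' One row per series and matched node with a present value, with columns
#' `series`, `node_id`, `value`, `p`.
#'
#' @param x A `binding_result` from [match_identifiers()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy binding_result
#' @export
tidy.binding_result <- function(x, ...) x$data

#' One-row summary of a binding result
#'
#' @param x A `binding_result`.
#' @param ... Unused.
#' @return A tibble with `n_series`, `n_matched_nodes`,
#'   `n_unmatched_identifiers` and `n_values` (bound series-node pairs).
#' @method glance binding_result
#' @export
glance.binding_result <- function(x, ...) {
  tibble(
    n_series = nrow(x$spec$series),
    n_matched_nodes = length(x$matched_node_ids),
    n_unmatched_identifiers = length(x$unmatched_identifiers),
    n_values = nrow(x$data)
  )
}

#' Tidy styled panels
#'
#' One row per panel and node, with the panel title, node geometry and the
#' resolved appearance.
#'
#' @param x A `pathway_panels` from [build_panels()].
#' @param ... Unused.
#' @return A tibble with columns `panel`, `node_id`, `label`, `kind`, `x`,
#'   `y`, `width`, `height`, `fill`, `visible`.
#' @export
tidy.pathway_panels <- function(x, ...) {
  purrr::map_dfr(x$panels, function(p) {
    dplyr::inner_join(
      dplyr::mutate(x$map$nodes, panel = p$title),
      p$appearances,
      by = "node_id"
    )
  })[, c(
    "panel", "node_id", "label", "kind", "x", "y",
    "width", "height", "fill", "visible"
  )]
}

#' Plot styled panels with ggplot2
#'
#' A quick-look companion to the SVG renderer: draws each panel as a facet,
#' nodes as rectangles filled with their resolved appearance colors and
#' edges as segments. Useful interactively; the publication output is
#' [render_svg()].
#'
#' @param object A `pathway_panels` from [build_panels()].
#' @param label_size Node label text size (mm); 0 suppresses labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_panels
#' @export
autoplot.pathway_panels <- function(object, label_size = 2, ...) {
  nodes <- tidy.pathway_panels(object)
  nodes$panel <- factor(nodes$panel, levels = purrr::map_chr(object$panels, "title"))
  nodes <- nodes[nodes$visible, ]

  centers <- object$map$nodes[, c("node_id", "x", "y")]
  edges <- purrr::map_dfr(object$panels, function(p) {
    e <- p$visible_edges
    e$panel <- p$title
    e
  })
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    edges$panel <- factor(edges$panel, levels = levels(nodes$panel))
    edges <- dplyr::left_join(edges, centers, by = c(source = "node_id"))
    edges <- dplyr::left_join(edges, centers,
      by = c(target = "node_id"), suffix = c("", "end")
    )
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      color = "grey40"
    )
  }
  p <- p +
    ggplot2::geom_rect(
      data = nodes,
      ggplot2::aes(
        xmin = .data$x - .data$width / 2, xmax = .data$x + .data$width / 2,
        ymin = .data$y - .data$height / 2, ymax = .data$y + .data$height / 2,
        fill = .data$fill
      ),
      color = "grey20"
    ) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 10))
  if (label_size > 0) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = label_size
    )
  }
  p
}
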