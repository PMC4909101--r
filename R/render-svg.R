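# Point where the segment from a rectangle's center toward (tx, ty) crosses
# the rectangle border; edges are drawn border-to-border, not center-to-center.
clip_to_border <- function(cx, cy, w, h, tx, ty) {
  dx <- tx - cx
  dy <- ty - cy
  if (dx == 0 && dy == 0) {
    return(c(cx, cy))
  }
  tx_scale <- if (dx != 0) (w / 2) / abs(dx) else Inf
  ty_scale <- if (dy != 0) (h / 2) / abs(dy) else Inf
  t <- min(tx_scale, ty_scale, 1)
  c(cx + t * dx, cy + t * dy)
}

svg_rect <- function(x, y, w, h, fill) {
  sprintf(
    '<rect x="%s" y="%s" width="%s" height="%s" rx="6" fill="%s" stroke="#333333" stroke-width="1" />',
    fmt_num(x), fmt_num(y), fmt_num(w), fmt_num(h), fill
  )
}

svg_text <- function(x, y, content, size, class = NULL) {
  sprintf(
    '<text%s x="%s" y="%s" text-anchor="middle" font-family="sans-serif" font-size="%s">%s</text>',
    if (is.null(class)) "" else sprintf(' class="%s"', class),
    fmt_num(x), fmt_num(y), fmt_num(size), xml_escape(content)
  )
}

svg_line <- function(x1, y1, x2, y2) {
  sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#666666" stroke-width="1" />',
    fmt_num(x1), fmt_num(y1), fmt_num(x2), fmt_num(y2)
  )
}

render_panel_group <- function(panel, nodes, origin_x, origin_y, title_height) {
  geo <- nodes
  geo$x <- geo$x + origin_x
  geo$y <- geo$y + origin_y
  app <- panel$appearances
  visible <- app$visible[match(geo$node_id, app$node_id)]
  fill <- app$fill[match(geo$node_id, app$node_id)]
  center <- stats::setNames(
    purrr::map(seq_len(nrow(geo)), function(i) geo[i, c("x", "y", "width", "height")]),
    geo$node_id
  )

  lines <- purrr::map_chr(seq_len(nrow(panel$visible_edges)), function(i) {
    e <- panel$visible_edges[i, ]
    s <- center[[e$source]]
    t <- center[[e$target]]
    p1 <- clip_to_border(s$x, s$y, s$width, s$height, t$x, t$y)
    p2 <- clip_to_border(t$x, t$y, t$width, t$height, s$x, s$y)
    svg_line(p1[1], p1[2], p2[1], p2[2])
  })

  drawn <- which(visible)
  rects <- purrr::map_chr(drawn, function(i) {
    svg_rect(
      geo$x[i] - geo$width[i] / 2, geo$y[i] - geo$height[i] / 2,
      geo$width[i], geo$height[i], fill[i]
    )
  })
  labels <- purrr::map_chr(drawn, function(i) {
    svg_text(geo$x[i], geo$y[i] + 3.5, geo$label[i], size = 10)
  })

  extent_w <- max(nodes$x + nodes$width / 2)
  title <- svg_text(
    origin_x + extent_w / 2, origin_y - title_height / 3,
    panel$title,
    size = 14, class = "panel-title"
  )
  paste(
    c(
      sprintf('<g class="panel" id="panel-%s">', xml_escape(panel$title)),
      title, lines, rects, labels, "</g>"
    ),
    collapse = "\n"
  )
}

render_legend <- function(style, x, y) {
  entries <- list(
    list(style$up_color, "up"),
    list(style$down_color, "down"),
    list(style$neutral_color, "no change"),
    list(style$no_data_color, "no data")
  )
  parts <- purrr::imap_chr(entries, function(e, i) {
    sx <- x + (i - 1) * 110
    paste(
      sprintf(
        '<rect x="%s" y="%s" width="18" height="12" rx="2" fill="%s" stroke="#333333" stroke-width="1" />',
        fmt_num(sx), fmt_num(y), e[[1]]
      ),
      sprintf(
        '<text x="%s" y="%s" text-anchor="start" font-family="sans-serif" font-size="11">%s</text>',
        fmt_num(sx + 24), fmt_num(y + 10), xml_escape(e[[2]])
      ),
      sep = "\n"
    )
  })
  paste(c('<g class="legend">', parts, "</g>"), collapse = "\n")
}

#' Render the small multiples to a standalone SVG document
#'
#' Composes the styled panels into one SVG 1.1 document: one top-level group
#' (`<g class="panel">`) per panel containing its title, a rounded rectangle
#' per visible node (at its map coordinates translated by the panel offset,
#' filled with the node's appearance color, labelled at its center) and a
#' line per visible edge between node borders; plus a single legend group.
#' The output is deterministic — identical inputs give byte-identical SVG.
#'
#' @param panels A `pathway_panels` object from [build_panels()].
#' @param grid A [grid_spec()].
#' @return An object of class `rendered_document`: a list with `svg_text`,
#'   `width` and `height`.
#' @examples
#' fx <- make_pathway(n_nodes = 4, n_edges = 3, seed = 1)
#' tbl <- make_measurements(fx$map, k_series = 2, seed = 1)$table
#' panels <- build_panels(fx$map, match_identifiers(fx$map, tbl), visual_style())
#' doc <- render_svg(panels)
#' doc$width
#' @export
render_svg <- function(panels, grid = grid_spec()) {
  stopifnot(inherits(panels, "pathway_panels"))
  map <- panels$map
  extent <- map_extent(map)
  k <- length(panels$panels)
  offsets <- layout_grid(k, extent[["width"]], extent[["height"]], grid)

  n_cols <- max(offsets$col)
  n_rows <- max(offsets$row)
  legend_height <- 30
  width <- 2 * grid$margin + n_cols * extent[["width"]] +
    (n_cols - 1) * grid$panel_gap
  width <- max(width, 2 * grid$margin + 4 * 110) # room for the legend row
  height <- grid$margin +
    n_rows * (extent[["height"]] + grid$title_height) +
    (n_rows - 1) * grid$panel_gap +
    legend_height + grid$margin

  groups <- purrr::map_chr(seq_len(k), function(i) {
    render_panel_group(
      panels$panels[[i]], map$nodes,
      offsets$x[i], offsets$y[i], grid$title_height
    )
  })
  legend_y <- height - grid$margin - 16
  legend <- render_legend(panels$style, grid$margin, legend_y)

  svg_text <- paste(
    c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
        fmt_num(width), fmt_num(height), fmt_num(width), fmt_num(height)
      ),
      groups,
      legend,
      "</svg>"
    ),
    collapse = "\n"
  )

  structure(
    list(svg_text = paste0(svg_text, "\n"), width = width, height = height),
    class = "rendered_document"
  )
}

#' @export
print.rendered_document <- function(x, ...) {
  cat(sprintf(
    "<rendered_document: SVG %g x %g, %d bytes>\n",
    x$width, x$height, nchar(x$svg_text, type = "bytes")
  ))
  invisible(x)
}

#' Write a rendered document to an SVG file
#'
#' @param doc A `rendered_document` from [render_svg()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) {
  stopifnot(inherits(doc, "rendered_document"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(doc$svg_text)), con)
  invisible(path)
}
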