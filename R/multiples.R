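#' Build one styled panel per sample series
#'
#' Replicates the map once per sample: every series in the binding result
#' yields one panel, in series order, holding an appearance (fill +
#' visibility) for every node of the template map and the subset of edges
#' whose endpoints are both visible in that panel (hiding a node also hides
#' its incident edges).
#'
#' In gradient mode with `value_max = "auto"`, the saturation point is the
#' maximum absolute value over *all* series jointly, so the panels share one
#' color scale and stay comparable.
#'
#' @param map The template [network_map()].
#' @param binding A `binding_result` from [match_identifiers()] on this map.
#' @param style A [visual_style()].
#' @return An object of class `pathway_panels`: a list with `panels` (each a
#'   list with `title`, `appearances` tibble, `visible_edges` tibble), plus
#'   the `map`, `style` and resolved `vmax`.
#' @examples
#' fx <- make_pathway(n_nodes = 6, n_edges = 5, seed = 1)
#' tbl <- make_measurements(fx$map, k_series = 3, seed = 1)$table
#' build_panels(fx$map, match_identifiers(fx$map, tbl), visual_style())
#' @export
build_panels <- function(map, binding, style = visual_style()) {
  stopifnot(
    inherits(map, "network_map"), inherits(binding, "binding_result"),
    inherits(style, "visual_style")
  )
  series <- binding$spec$series
  if (nrow(series) == 0) stop_config("no samples to render")
  if (style$mode == "p_value_cutoff") {
    bare <- series$name[is.na(series$p_column)]
    if (length(bare) > 0) {
      stop_config(
        "p_value_cutoff mode needs a p-value column for every series; ",
        "missing for: ", paste(bare, collapse = ", ")
      )
    }
  }

  vmax <- style$value_max
  if (identical(vmax, "auto")) {
    vmax <- if (nrow(binding$data) > 0) max(abs(binding$data$value)) else 1
    if (!is.finite(vmax) || vmax == 0) vmax <- 1
  }

  nodes <- map$nodes
  panels <- purrr::map(seq_len(nrow(series)), function(i) {
    s <- series[i, ]
    d <- dplyr::filter(binding$data, .data$series == s$name)
    row <- match(nodes$node_id, d$node_id)
    app <- node_appearance(
      kind = nodes$kind,
      value = d$value[row],
      p = d$p[row],
      style = style, vmax = vmax
    )
    appearances <- dplyr::bind_cols(tibble(node_id = nodes$node_id), app)
    visible_ids <- appearances$node_id[appearances$visible]
    visible_edges <- dplyr::filter(
      map$edges,
      .data$source %in% visible_ids & .data$target %in% visible_ids
    )
    list(title = s$name, appearances = appearances, visible_edges = visible_edges)
  })

  structure(
    list(panels = panels, map = map, style = style, vmax = vmax),
    class = "pathway_panels"
  )
}

#' @export
print.pathway_panels <- function(x, ...) {
  cat(sprintf(
    "<pathway_panels: %d panel(s) over %d-node map (%s mode, vmax %g)>\n",
    length(x$panels), nrow(x$map$nodes), x$style$mode, x$vmax
  ))
  invisible(x)
}

#' Grid parameters for composing panels
#'
#' @param n_cols `"auto"` (the near-square `ceiling(sqrt(k))`) or a positive
#'   integer number of columns.
#' @param panel_gap Gap between adjacent panels, canvas units.
#' @param margin Outer margin, canvas units.
#' @param title_height Vertical space reserved above each panel for its
#'   title, canvas units.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_cols = "auto", panel_gap = 30, margin = 20,
                      title_height = 24) {
  if (!identical(n_cols, "auto")) {
    n_cols <- as.integer(n_cols)
    if (is.na(n_cols) || n_cols < 1) stop_config("n_cols must be >= 1 or \"auto\"")
  }
  stopifnot(panel_gap >= 0, margin >= 0, title_height >= 0)
  structure(
    list(
      n_cols = n_cols, panel_gap = panel_gap, margin = margin,
      title_height = title_height
    ),
    class = "grid_spec"
  )
}

#' Compute panel origins in the small-multiples grid
#'
#' Places `k` panels row-major in a grid. Each origin is the point where the
#' template map's (0, 0) lands; titles sit in the `title_height` band just
#' above each panel.
#'
#' @param k Number of panels (>= 1).
#' @param template_width,template_height Extent of the template map.
#' @param grid A [grid_spec()].
#' @return A tibble with columns `panel`, `row`, `col`, `x`, `y`.
#' @examples
#' layout_grid(5, 300, 200, grid_spec(n_cols = 3))
#' @export
layout_grid <- function(k, template_width, template_height, grid = grid_spec()) {
  stopifnot(k >= 1)
  n_cols <- if (identical(grid$n_cols, "auto")) ceiling(sqrt(k)) else grid$n_cols
  idx <- seq_len(k) - 1L
  row0 <- idx %/% n_cols
  col0 <- idx %% n_cols
  tibble(
    panel = seq_len(k),
    row = as.integer(row0 + 1L),
    col = as.integer(col0 + 1L),
    x = grid$margin + col0 * (template_width + grid$panel_gap),
    y = grid$margin + grid$title_height +
      row0 * (template_height + grid$title_height + grid$panel_gap)
  )
}
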