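fixture_panels <- function(n_nodes = 8, n_edges = 8, k_series = 3, seed = 11,
                           style = visual_style(), ...) {
  fx <- make_pathway(n_nodes = n_nodes, n_edges = n_edges, seed = seed)
  tbl <- make_measurements(fx$map, k_series = k_series, seed = seed, ...)$table
  build_panels(fx$map, match_identifiers(fx$map, tbl), style)
}

test_that("build_panels makes one panel per series, in series order", {
  panels <- fixture_panels(k_series = 5)
  expect_length(panels$panels, 5L)
  expect_identical(
    vapply(panels$panels, `[[`, character(1), "title"),
    c("0h", "2h", "12h", "24h", "72h")
  )
  one <- fixture_panels(k_series = 1)
  expect_length(one$panels, 1L)
  # every node of the template has exactly one appearance per panel
  for (p in panels$panels) {
    expect_setequal(p$appearances$node_id, panels$map$nodes$node_id)
  }
})

test_that("build_panels refuses value-only series in significance mode", {
  fx <- make_pathway(n_nodes = 5, n_edges = 4, seed = 2)
  tbl <- make_measurements(fx$map, k_series = 3, with_p = FALSE, seed = 2)$table
  binding <- match_identifiers(fx$map, tbl)
  expect_error(
    build_panels(fx$map, binding, visual_style(mode = "p_value_cutoff")),
    "s1, s2, s3"
  )
})

test_that("auto value_max is the joint maximum |value| across all series", {
  fx <- make_pathway(n_nodes = 6, n_edges = 5, seed = 9)
  tbl <- make_measurements(fx$map, k_series = 3, seed = 9, frac_unmatched = 0)$table
  binding <- match_identifiers(fx$map, tbl)
  panels2 <- build_panels(fx$map, binding, visual_style())
  expect_identical(panels2$vmax, max(abs(binding$data$value)))
})

test_that("hiding a node also hides its incident edges", {
  fx <- make_pathway(n_nodes = 6, n_edges = 8, seed = 5)
  tbl <- make_measurements(fx$map,
    k_series = 2, frac_unmatched = 0.5, seed = 5
  )$table
  binding <- match_identifiers(fx$map, tbl)
  panels <- build_panels(
    fx$map, binding,
    visual_style(no_data_policy = "hide")
  )
  for (p in panels$panels) {
    hidden <- p$appearances$node_id[!p$appearances$visible]
    expect_gt(length(hidden), 0) # the fixture does unbind some nodes
    expect_false(any(p$visible_edges$source %in% hidden))
    expect_false(any(p$visible_edges$target %in% hidden))
  }
})

test_that("layout_grid places panels row-major with the documented defaults", {
  g <- grid_spec(n_cols = 3, panel_gap = 10, margin = 20, title_height = 24)
  off <- layout_grid(5, 300, 200, g)
  expect_identical(max(off$row), 2L) # ceil(5 / 3)
  expect_identical(sum(off$row == 1), 3L)
  expect_identical(sum(off$row == 2), 2L)

  one <- layout_grid(1, 300, 200, g)
  expect_identical(one$x, 20)
  expect_identical(one$y, 20 + 24)

  auto <- layout_grid(4, 100, 100, grid_spec())
  expect_identical(max(auto$col), 2L) # ceil(sqrt(4)) = 2 -> 2 x 2
  expect_identical(max(auto$row), 2L)
})

test_that("render_svg emits one well-formed panel group per sample plus a legend", {
  panels <- fixture_panels(k_series = 3)
  doc <- render_svg(panels)
  x <- svg_xml(doc) # strict parse; fails the test if not well-formed XML
  expect_identical(xml2::xml_name(x), "svg")
  expect_length(svg_panel_groups(doc), 3L)
  legend <- xml2::xml_find_all(x, "//*[local-name()='g' and @class='legend']")
  expect_length(legend, 1L)
  expect_identical(
    as.numeric(xml2::xml_attr(x, "width")), doc$width
  )
})

test_that("a node hidden in one panel keeps its rectangle in the others", {
  fx <- make_pathway(n_nodes = 4, n_edges = 3, seed = 3)
  tbl <- tibble::tibble(
    id = c("G1", "G2", "G3", "G4"),
    a = c(1, 1, 1, 1),
    b = c(NA, 1, 1, 1),
    c = c(1, 1, 1, 1)
  )
  attr(tbl, "id_column") <- "id"
  binding <- match_identifiers(fx$map, tbl)
  panels <- build_panels(fx$map, binding, visual_style(no_data_policy = "hide"))
  doc <- render_svg(panels)
  rect_counts <- vapply(svg_panel_groups(doc), function(g) length(group_rects(g)), integer(1))
  expect_identical(rect_counts, c(4L, 3L, 4L))
})

test_that("a node's rectangle has identical size and within-panel position in every panel", {
  panels <- fixture_panels(k_series = 4, seed = 8)
  doc <- render_svg(panels)
  groups <- svg_panel_groups(doc)
  geo <- lapply(groups, function(g) {
    r <- group_rects(g)
    data.frame(
      x = as.numeric(xml2::xml_attr(r, "x")),
      y = as.numeric(xml2::xml_attr(r, "y")),
      w = as.numeric(xml2::xml_attr(r, "width")),
      h = as.numeric(xml2::xml_attr(r, "height"))
    )
  })
  origins <- layout_grid(
    length(groups),
    max(panels$map$nodes$x + panels$map$nodes$width / 2),
    max(panels$map$nodes$y + panels$map$nodes$height / 2),
    grid_spec()
  )
  for (i in seq_along(geo)) {
    rel <- geo[[i]]
    rel$x <- rel$x - origins$x[i]
    rel$y <- rel$y - origins$y[i]
    expect_equal(rel, local({
      r1 <- geo[[1]]
      r1$x <- r1$x - origins$x[1]
      r1$y <- r1$y - origins$y[1]
      r1
    }))
  }
})

test_that("rendering is deterministic to the byte", {
  a <- render_svg(fixture_panels(seed = 13))
  b <- render_svg(fixture_panels(seed = 13))
  expect_identical(a$svg_text, b$svg_text)
})

test_that("no rendered line dangles: endpoints touch rendered rectangles", {
  panels <- fixture_panels(
    k_series = 2, seed = 19, frac_unmatched = 0.4,
    style = visual_style(no_data_policy = "hide")
  )
  doc <- render_svg(panels)
  for (g in svg_panel_groups(doc)) {
    rects <- group_rects(g)
    rx <- as.numeric(xml2::xml_attr(rects, "x"))
    ry <- as.numeric(xml2::xml_attr(rects, "y"))
    rw <- as.numeric(xml2::xml_attr(rects, "width"))
    rh <- as.numeric(xml2::xml_attr(rects, "height"))
    inside_some_rect <- function(px, py) {
      any(px >= rx - 0.51 & px <= rx + rw + 0.51 &
        py >= ry - 0.51 & py <= ry + rh + 0.51)
    }
    for (l in group_lines(g)) {
      expect_true(inside_some_rect(
        as.numeric(xml2::xml_attr(l, "x1")), as.numeric(xml2::xml_attr(l, "y1"))
      ))
      expect_true(inside_some_rect(
        as.numeric(xml2::xml_attr(l, "x2")), as.numeric(xml2::xml_attr(l, "y2"))
      ))
    }
  }
})

test_that("tidy and autoplot expose the panel structure", {
  panels <- fixture_panels(k_series = 2)
  td <- tidy(panels)
  expect_identical(nrow(td), 2L * nrow(panels$map$nodes))
  expect_true(all(c("panel", "fill", "visible") %in% names(td)))
  p <- ggplot2::autoplot(panels)
  expect_s3_class(p, "ggplot")
})
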