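#' The preset p-value cutoffs
#'
#' The significance mode exposes four preset thresholds; [visual_style()]
#' accepts any value in (0, 1] but these are the conventional choices.
#'
#' @return A numeric vector: 0.001, 0.01, 0.05, 0.1.
#' @export
cutoff_presets <- function() c(0.001, 0.01, 0.05, 0.1)

#' Define the visual style of the small multiples
#'
#' Controls how a node's datum (or the absence of one) becomes a fill color.
#' Two modes exist:
#' * `fold_change_gradient` — the signed value is mapped through a symmetric
#'   two-color gradient: `down_color` at `-value_max`, `neutral_color` at 0,
#'   `up_color` at `+value_max`, linear per RGB channel in between and
#'   clamped beyond.
#' * `p_value_cutoff` — a node is colored `up_color`/`down_color` by the sign
#'   of its value only when `p <= cutoff`, else `neutral_color`.
#'
#' @param up_color Fill for up-regulation, `#RRGGBB`. Default `"#00FF00"`
#'   (green), the conventional color for up-regulated genes.
#' @param down_color Fill for down-regulation. Default `"#FF0000"` (red).
#' @param neutral_color Fill for "no change" / not significant. Default white.
#' @param no_data_color Fill for greyed-out nodes. Default `"#C0C0C0"`.
#' @param mode `"fold_change_gradient"` or `"p_value_cutoff"`.
#' @param cutoff Significance threshold in (0, 1], inclusive ("significant"
#'   means `p <= cutoff`). See [cutoff_presets()] for the conventional
#'   values; default 0.05.
#' @param no_data_policy How nodes without bound data are drawn: `"show"`
#'   (default; drawn with their neutral fill), `"grey"` (filled with
#'   `no_data_color`) or `"hide"` (not drawn, and their incident edges are
#'   dropped too). Decoration nodes are always greyed, never hidden.
#' @param value_max `"auto"` (the gradient saturates at the largest absolute
#'   value across *all* series, so every panel shares one scale) or a
#'   positive number.
#' @return An object of class `visual_style`.
#' @examples
#' visual_style(mode = "p_value_cutoff", cutoff = 0.1, no_data_policy = "grey")
#' @export
visual_style <- function(up_color = "#00FF00",
                         down_color = "#FF0000",
                         neutral_color = "#FFFFFF",
                         no_data_color = "#C0C0C0",
                         mode = c("fold_change_gradient", "p_value_cutoff"),
                         cutoff = 0.05,
                         no_data_policy = c("show", "grey", "hide"),
                         value_max = "auto") {
  mode <- match.arg(mode)
  no_data_policy <- match.arg(no_data_policy)
  for (col in list(up_color, down_color, neutral_color, no_data_color)) {
    if (!is_hex_color(col)) {
      stop_config("colors must be #RRGGBB hex strings, got '", col, "'")
    }
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 1) {
    stop_config("cutoff must be a single number in (0, 1]")
  }
  if (!identical(value_max, "auto") &&
    (!is.numeric(value_max) || length(value_max) != 1 || value_max <= 0)) {
    stop_config("value_max must be \"auto\" or a positive number")
  }
  structure(
    list(
      up_color = toupper(up_color), down_color = toupper(down_color),
      neutral_color = toupper(neutral_color),
      no_data_color = toupper(no_data_color),
      mode = mode, cutoff = cutoff, no_data_policy = no_data_policy,
      value_max = value_max
    ),
    class = "visual_style"
  )
}

#' @export
print.visual_style <- function(x, ...) {
  cat(sprintf(
    "<visual_style: %s | up %s, down %s, neutral %s, no-data %s | cutoff %g | policy %s | vmax %s>\n",
    x$mode, x$up_color, x$down_color, x$neutral_color, x$no_data_color,
    x$cutoff, x$no_data_policy,
    if (identical(x$value_max, "auto")) "auto" else format(x$value_max)
  ))
  invisible(x)
}

hex_to_rgb <- function(hex) as.numeric(grDevices::col2rgb(hex))

rgb_to_hex <- function(m) sprintf("#%02X%02X%02X", m[, 1], m[, 2], m[, 3])

#' Gradient color for a signed value
#'
#' Piecewise-linear interpolation per RGB channel: values at or below `-vmax`
#' give `down_color`, 0 gives `neutral_color`, values at or above `+vmax`
#' give `up_color`; intermediates interpolate linearly between the adjacent
#' anchors. Channels are rounded half-up to integers.
#'
#' @param value Signed numeric vector (e.g. log2 fold changes); must be
#'   finite — missing values are a no-data matter handled upstream.
#' @param style A [visual_style()].
#' @param vmax Saturation point (> 0); defaults to the style's numeric
#'   `value_max`.
#' @return Character vector of `#RRGGBB` strings.
#' @examples
#' color_for_value(c(-2, 0, 1, 2), visual_style(), vmax = 2)
#' @export
color_for_value <- function(value, style = visual_style(), vmax = NULL) {
  vmax <- vmax %||% style$value_max
  if (!is.numeric(vmax) || vmax <= 0) {
    stop("vmax must be a positive number (resolve value_max=\"auto\" first)",
      call. = FALSE
    )
  }
  if (any(!is.finite(value))) {
    stop("color_for_value requires finite values; treat missing data upstream",
      call. = FALSE
    )
  }
  up <- hex_to_rgb(style$up_color)
  down <- hex_to_rgb(style$down_color)
  neutral <- hex_to_rgb(style$neutral_color)

  t <- pmin(1, pmax(-1, value / vmax))
  m <- matrix(0, nrow = length(t), ncol = 3)
  for (k in 1:3) {
    m[, k] <- ifelse(
      t >= 0,
      neutral[k] + t * (up[k] - neutral[k]),
      neutral[k] - t * (down[k] - neutral[k])
    )
  }
  rgb_to_hex(matrix(floor(m + 0.5), ncol = 3)) # round half-up
}

#' Significance color for a (value, p) pair
#'
#' The step-function coloring: when `p <= cutoff` the node takes
#' `up_color` or `down_color` by the sign of its value (neutral when the
#' value is exactly 0, since there is no direction); when `p > cutoff` the
#' node is neutral regardless of the value.
#'
#' @param value Signed numeric vector.
#' @param p Numeric vector of p-values in \[0, 1\], same length.
#' @param style A [visual_style()]; only its colors and `cutoff` are used.
#' @return Character vector of `#RRGGBB` strings.
#' @examples
#' style <- visual_style(cutoff = 0.1)
#' color_for_significance(c(2, -1.5, 0), c(0.01, 0.2, 0.001), style)
#' @export
color_for_significance <- function(value, p, style = visual_style()) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p must be present and in [0, 1]; series without p-values cannot ",
      "be colored in p_value_cutoff mode",
      call. = FALSE
    )
  }
  out <- rep(style$neutral_color, length(value))
  sig <- p <= style$cutoff
  out[sig & value > 0] <- style$up_color
  out[sig & value < 0] <- style$down_color
  out
}

#' Resolve fill and visibility for nodes of one panel
#'
#' Vectorized appearance rule combining the no-data policy with the coloring
#' mode. Decoration nodes are always filled with `no_data_color` and are
#' never hidden. Data nodes without a datum (no matching identifier, missing
#' value cell, or — in significance mode — missing p-value) follow the
#' no-data policy: shown with the neutral fill, greyed, or hidden. Data
#' nodes with a datum are filled via [color_for_value()] or
#' [color_for_significance()] according to the style's mode.
#'
#' @param kind Character vector, `"data_node"` or `"decoration"`.
#' @param value,p Numeric vectors aligned with `kind` (`NA` = absent).
#' @param style A [visual_style()].
#' @param vmax Resolved gradient saturation (used in gradient mode).
#' @return A tibble with columns `fill` (`#RRGGBB`) and `visible` (logical).
#' @export
node_appearance <- function(kind, value, p = NA_real_, style = visual_style(),
                            vmax = NULL) {
  n <- length(kind)
  value <- rep_len(value, n)
  p <- rep_len(p, n)

  decoration <- kind == "decoration"
  has_datum <- !decoration & !is.na(value) &
    (style$mode != "p_value_cutoff" | !is.na(p))

  fill <- rep(style$neutral_color, n)
  visible <- rep(TRUE, n)

  no_data <- !decoration & !has_datum
  if (style$no_data_policy == "grey") fill[no_data] <- style$no_data_color
  if (style$no_data_policy == "hide") visible[no_data] <- FALSE
  fill[decoration] <- style$no_data_color

  if (any(has_datum)) {
    fill[has_datum] <- switch(style$mode,
      fold_change_gradient = color_for_value(value[has_datum], style, vmax),
      p_value_cutoff = color_for_significance(value[has_datum], p[has_datum], style)
    )
  }
  tibble(fill = fill, visible = visible)
}
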