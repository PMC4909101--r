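#' Construct a pathway/network map
#'
#' A `network_map` is the template that gets replicated once per sample in the
#' small-multiples output. It holds a node table with canvas geometry (origin
#' top-left, y growing downward, matching SVG) and an edge table whose
#' endpoints must resolve against the node table.
#'
#' @param name Map name (shown nowhere in the rendering; kept for provenance).
#' @param nodes A data frame with columns `node_id`, `label`, `kind`
#'   (`"data_node"` or `"decoration"`), `x`, `y` (node center), `width`,
#'   `height` (all canvas units), and optionally `xref_db`, `xref_id`
#'   (cross-reference database and identifier, e.g. from a GPML `Xref`).
#' @param edges A data frame with columns `source` and `target` holding node
#'   ids, or `NULL` for an edgeless map.
#'
#' @return An object of class `network_map`: a list with elements `name`,
#'   `nodes` (tibble) and `edges` (tibble).
#'
#' @details Only `data_node` rows can ever receive measurement data;
#'   `decoration` rows (labels, shapes) are rendered greyed and are never
#'   bound or hidden.
#'
#' @examples
#' map <- network_map(
#'   "toy",
#'   data.frame(
#'     node_id = c("a", "b"), label = c("G1", "G2"), kind = "data_node",
#'     x = c(50, 200), y = 20, width = 80, height = 25
#'   ),
#'   data.frame(source = "a", target = "b")
#' )
#' map$nodes
#' @export
network_map <- function(name, nodes, edges = NULL) {
  nodes <- as_tibble(nodes)
  required <- c("node_id", "label", "kind", "x", "y", "width", "height")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("nodes is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"xref_db" %in% names(nodes)) nodes$xref_db <- NA_character_
  if (!"xref_id" %in% names(nodes)) nodes$xref_id <- NA_character_
  nodes <- nodes[, c(required, "xref_db", "xref_id")]
  nodes$node_id <- as.character(nodes$node_id)
  nodes$label <- as.character(nodes$label)

  if (nrow(nodes) == 0) stop("a map needs at least one node", call. = FALSE)
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id: ", nodes$node_id[duplicated(nodes$node_id)][1],
      call. = FALSE
    )
  }
  if (!all(nodes$kind %in% c("data_node", "decoration"))) {
    stop("node kind must be 'data_node' or 'decoration'", call. = FALSE)
  }
  if (any(!is.finite(nodes$width)) || any(nodes$width <= 0) ||
    any(!is.finite(nodes$height)) || any(nodes$height <= 0)) {
    stop("node width and height must be positive", call. = FALSE)
  }

  if (is.null(edges)) {
    edges <- tibble(source = character(), target = character())
  }
  edges <- as_tibble(edges)
  if (!all(c("source", "target") %in% names(edges))) {
    stop("edges needs columns 'source' and 'target'", call. = FALSE)
  }
  edges <- edges[, c("source", "target")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  unresolved <- setdiff(c(edges$source, edges$target), nodes$node_id)
  if (length(unresolved) > 0) {
    stop("edge endpoint(s) not in node set: ",
      paste(unresolved, collapse = ", "),
      call. = FALSE
    )
  }

  structure(
    list(name = as.character(name), nodes = nodes, edges = edges),
    class = "network_map"
  )
}

#' @export
print.network_map <- function(x, ...) {
  n_data <- sum(x$nodes$kind == "data_node")
  cat(sprintf(
    "<network_map '%s': %d nodes (%d data, %d decoration), %d edges>\n",
    x$name, nrow(x$nodes), n_data, nrow(x$nodes) - n_data, nrow(x$edges)
  ))
  invisible(x)
}

# Shift all node centers so the bounding box of node rectangles starts at
# (0, 0). Coordinates are otherwise taken as-is (y grows downward, like SVG).
normalize_origin <- function(map) {
  dx <- min(map$nodes$x - map$nodes$width / 2)
  dy <- min(map$nodes$y - map$nodes$height / 2)
  map$nodes$x <- map$nodes$x - dx
  map$nodes$y <- map$nodes$y - dy
  map
}

# Extent of the node bounding box, assuming a normalized origin.
map_extent <- function(map) {
  c(
    width = max(map$nodes$x + map$nodes$width / 2),
    height = max(map$nodes$y + map$nodes$height / 2)
  )
}
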