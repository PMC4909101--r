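# Deterministic fallback layout for formats that carry no coordinates:
# nodes on a circle whose radius grows with the node count, in order of
# first appearance, then translated so the bounding box starts at (0, 0).
circle_layout <- function(n) {
  r <- max(80, 18 * n)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  list(x = r * cos(theta), y = r * sin(theta))
}

#' Read a plain network (SIF or GraphML) as a map
#'
#' Reads a network without pathway semantics into a [network_map()]. All
#' nodes are bindable (`kind = "data_node"`). SIF carries no geometry, and
#' GraphML often none either; in that case nodes are placed deterministically
#' on a circle (radius proportional to node count) in order of first
#' appearance, so repeated reads of the same file give identical coordinates.
#'
#' SIF lines are whitespace-delimited `source relation target [target ...]`
#' records; a single-token line declares an isolated node. GraphML node
#' positions are honored when the file defines keys named `x` and `y`
#' (by key id or `attr.name`).
#'
#' @param x Path to the file or the literal file text.
#' @param format `"sif"` or `"graphml"`.
#' @param name Map name; defaults to the format name.
#' @return A [network_map()].
#' @examples
#' read_simple_network("A pp B\nB pp C", format = "sif")
#' @export
read_simple_network <- function(x, format = c("sif", "graphml"), name = NULL) {
  format <- match.arg(format)
  switch(format,
    sif = read_sif(x, name %||% "sif network"),
    graphml = read_graphml(x, name %||% "graphml network")
  )
}

read_sif <- function(x, name) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- strsplit(paste(x, collapse = "\n"), "\r\n|\n|\r")[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty SIF input", call. = FALSE)

  ids <- character()
  src <- character()
  tgt <- character()
  for (i in seq_along(lines)) {
    tokens <- stringr::str_split(stringr::str_trim(lines[i]), "[[:space:]]+")[[1]]
    if (length(tokens) == 1L) {
      ids <- union(ids, tokens)
    } else if (length(tokens) == 2L) {
      stop("malformed SIF line ", i,
        ": got a source and relation but no target",
        call. = FALSE
      )
    } else {
      ids <- union(ids, c(tokens[1], tokens[-(1:2)]))
      src <- c(src, rep(tokens[1], length(tokens) - 2L))
      tgt <- c(tgt, tokens[-(1:2)])
    }
  }

  pos <- circle_layout(length(ids))
  nodes <- tibble(
    node_id = ids, label = ids, kind = "data_node",
    x = pos$x, y = pos$y, width = 80, height = 25
  )
  normalize_origin(
    network_map(name, nodes, tibble(source = src, target = tgt))
  )
}

read_graphml <- function(x, name) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e) {
    stop("not well-formed GraphML XML: ", conditionMessage(e), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)

  # resolve <key> definitions so positions can be given by id or attr.name
  keys <- xml2::xml_find_all(doc, ".//key")
  key_name <- stats::setNames(
    dplyr::coalesce(xml2::xml_attr(keys, "attr.name"), xml2::xml_attr(keys, "id")),
    xml2::xml_attr(keys, "id")
  )
  data_value <- function(el, wanted) {
    data <- xml2::xml_find_all(el, "./data")
    ref <- xml2::xml_attr(data, "key")
    resolved <- ifelse(ref %in% names(key_name), key_name[ref], ref)
    hit <- which(resolved == wanted)
    if (length(hit) == 0) {
      return(NA_character_)
    }
    xml2::xml_text(data[[hit[1]]])
  }

  node_els <- xml2::xml_find_all(doc, ".//graph/node")
  if (length(node_els) == 0) stop("GraphML file contains no nodes", call. = FALSE)
  ids <- xml2::xml_attr(node_els, "id")
  labels <- purrr::map_chr(node_els, data_value, wanted = "label")
  labels <- dplyr::coalesce(labels, ids)
  xs <- as.numeric(purrr::map_chr(node_els, data_value, wanted = "x"))
  ys <- as.numeric(purrr::map_chr(node_els, data_value, wanted = "y"))
  if (anyNA(xs) || anyNA(ys)) {
    pos <- circle_layout(length(ids))
    xs <- pos$x
    ys <- pos$y
  }

  edge_els <- xml2::xml_find_all(doc, ".//graph/edge")
  edges <- tibble(
    source = xml2::xml_attr(edge_els, "source"),
    target = xml2::xml_attr(edge_els, "target")
  )

  nodes <- tibble(
    node_id = ids, label = labels, kind = "data_node",
    x = xs, y = ys, width = 80, height = 25
  )
  normalize_origin(network_map(name, nodes, edges))
}
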