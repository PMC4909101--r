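GPML_NS <- "http://pathvisio.org/GPML/2013a"

#' Read a GPML pathway map
#'
#' Parses a pathway in the GPML dialect used by WikiPathways and PathVisio
#' into a [network_map()]. `DataNode` elements become bindable data nodes
#' with their `TextLabel`, center/size geometry from their `Graphics` child
#' and any `Xref` database/id; `Label` and `Shape` elements become
#' decoration nodes, which are rendered greyed and never receive data.
#' `Interaction` and `GraphicalLine` elements whose first and last `Point`
#' reference node `GraphId`s become edges; endpoints referencing anchors or
#' unknown ids are dropped with a warning. `Group` containers are flattened:
#' member nodes are kept, the group itself is ignored (data binds to leaf
#' nodes).
#'
#' Coordinates are taken as-is (origin top-left, y growing downward, matching
#' SVG), except for a uniform translation so the map's bounding box starts at
#' (0, 0).
#'
#' @param x Path to a `.gpml` file, a literal XML string, or an
#'   `xml2::xml_document`.
#' @return A [network_map()].
#' @export
read_gpml <- function(x) {
  doc <- if (inherits(x, "xml_document")) {
    x
  } else {
    tryCatch(xml2::read_xml(x), error = function(e) {
      stop("not well-formed XML: ", conditionMessage(e), call. = FALSE)
    })
  }
  ns_uris <- unlist(xml2::xml_ns(doc))
  if (!any(grepl("pathvisio.org/GPML", ns_uris, fixed = TRUE))) {
    stop("missing GPML namespace (expected ", GPML_NS, ")", call. = FALSE)
  }
  xml2::xml_ns_strip(doc)
  name <- xml2::xml_attr(doc, "Name")
  if (is.na(name)) name <- "pathway"

  auto_id <- local({
    k <- 0L
    function() {
      k <<- k + 1L
      sprintf(".anon%d", k)
    }
  })

  parse_node <- function(el, kind) {
    graphics <- xml2::xml_find_first(el, "./Graphics")
    if (inherits(graphics, "xml_missing")) {
      if (kind == "data_node") {
        stop(
          "DataNode '", xml2::xml_attr(el, "TextLabel"),
          "' has no Graphics element (at ", xml2::xml_path(el), ")",
          call. = FALSE
        )
      }
      return(NULL) # geometry-less decoration: nothing to draw
    }
    geo <- unname(vapply(
      c("CenterX", "CenterY", "Width", "Height"),
      function(a) as.numeric(xml2::xml_attr(graphics, a)),
      numeric(1)
    ))
    xref <- xml2::xml_find_first(el, "./Xref")
    id <- xml2::xml_attr(el, "GraphId")
    label <- xml2::xml_attr(el, "TextLabel")
    tibble(
      node_id = if (is.na(id)) auto_id() else id,
      label = if (is.na(label)) "" else label,
      kind = kind,
      x = geo[1], y = geo[2], width = geo[3], height = geo[4],
      xref_db = xml2::xml_attr(xref, "Database"),
      xref_id = xml2::xml_attr(xref, "ID")
    )
  }

  nodes <- dplyr::bind_rows(
    purrr::map(xml2::xml_find_all(doc, ".//DataNode"), parse_node, kind = "data_node"),
    purrr::map(xml2::xml_find_all(doc, ".//Label"), parse_node, kind = "decoration"),
    purrr::map(xml2::xml_find_all(doc, ".//Shape"), parse_node, kind = "decoration")
  )
  if (nrow(nodes) == 0) stop("GPML pathway contains no nodes", call. = FALSE)

  lines <- xml2::xml_find_all(doc, ".//Interaction | .//GraphicalLine")
  edges <- purrr::map(lines, function(el) {
    pts <- xml2::xml_find_all(el, ".//Point")
    refs <- xml2::xml_attr(pts, "GraphRef")
    if (length(refs) < 2) refs <- c(NA_character_, NA_character_)
    ends <- c(refs[1], refs[length(refs)])
    if (anyNA(ends) || !all(ends %in% nodes$node_id)) {
      warning("dropping interaction with unresolvable endpoint(s): ",
        paste(ends, collapse = " -> "),
        call. = FALSE
      )
      return(NULL)
    }
    tibble(source = ends[1], target = ends[2])
  })
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0) edges <- NULL

  normalize_origin(network_map(name, nodes, edges))
}

# %.17g keeps coordinates exact through a write/read round trip.
num17 <- function(x) sprintf("%.17g", x)

# Geometry attributes for one node, as GPML attribute text.
gpml_graphics <- function(n) {
  sprintf(
    '<Graphics CenterX="%s" CenterY="%s" Width="%s" Height="%s" />',
    num17(n$x), num17(n$y), num17(n$width), num17(n$height)
  )
}

#' Write a map as GPML text
#'
#' Serializes a [network_map()] to a GPML (2013a namespace) document. Data
#' nodes become `DataNode` elements, decorations become `Label` elements, and
#' edges become `Interaction` elements with two `Point`s referencing the
#' endpoint `GraphId`s. The output re-reads with [read_gpml()] to a map with
#' identical node/edge counts, labels and coordinates.
#'
#' @param map A [network_map()].
#' @param path Optional file path; when given the text is also written there.
#' @return The GPML text, invisibly when `path` is given.
#' @export
write_gpml <- function(map, path = NULL) {
  nodes <- map$nodes
  node_xml <- purrr::map_chr(seq_len(nrow(nodes)), function(i) {
    n <- nodes[i, ]
    tag <- if (n$kind == "data_node") "DataNode" else "Label"
    xref <- if (n$kind == "data_node" && !is.na(n$xref_db)) {
      sprintf(
        '\n    <Xref Database="%s" ID="%s" />',
        xml_escape(n$xref_db), xml_escape(n$xref_id)
      )
    } else {
      ""
    }
    sprintf(
      '  <%s TextLabel="%s" GraphId="%s">\n    %s%s\n  </%s>',
      tag, xml_escape(n$label), xml_escape(n$node_id),
      gpml_graphics(n), xref, tag
    )
  })

  centers <- stats::setNames(
    purrr::map(seq_len(nrow(nodes)), function(i) nodes[i, c("x", "y")]),
    nodes$node_id
  )
  edge_xml <- purrr::map_chr(seq_len(nrow(map$edges)), function(i) {
    e <- map$edges[i, ]
    s <- centers[[e$source]]
    t <- centers[[e$target]]
    sprintf(
      paste0(
        "  <Interaction>\n    <Graphics>\n",
        '      <Point GraphRef="%s" X="%s" Y="%s" />\n',
        '      <Point GraphRef="%s" X="%s" Y="%s" />\n',
        "    </Graphics>\n  </Interaction>"
      ),
      xml_escape(e$source), num17(s$x), num17(s$y),
      xml_escape(e$target), num17(t$x), num17(t$y)
    )
  })

  extent <- map_extent(map)
  text <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf(
      '<Pathway xmlns="%s" Name="%s" Version="%s">\n',
      GPML_NS, xml_escape(map$name), "pathpanels"
    ),
    sprintf(
      '  <Graphics BoardWidth="%s" BoardHeight="%s" />\n',
      num17(extent[["width"]]), num17(extent[["height"]])
    ),
    paste(c(node_xml, edge_xml), collapse = "\n"),
    "\n</Pathway>\n"
  )
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}
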