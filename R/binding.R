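#' Describe how table columns bind to map nodes
#'
#' A binding spec names the identifier column, the ordered sample series
#' (each a value column with an optional p-value column) and the node
#' attribute used as the matching key. [auto_bind()] builds one from column
#' order; this constructor is the manual path for tables whose layout the
#' auto rule cannot express.
#'
#' @param id_column Header name of the identifier column.
#' @param value_columns Character vector of value-column names, in panel
#'   order. Each becomes one sample series, named after its value column.
#' @param p_columns `NULL` (no p-values), or a character vector the same
#'   length as `value_columns`; use `NA` for series without a p-value column.
#' @param match_attribute Node attribute matched against identifiers:
#'   `"label"` (default), `"node_id"`, `"xref_id"` or `"xref_db"`.
#' @return An object of class `binding_spec`: a list with `id_column`,
#'   `series` (a tibble with columns `name`, `value_column`, `p_column`) and
#'   `match_attribute`.
#' @export
binding_spec <- function(id_column, value_columns, p_columns = NULL,
                         match_attribute = "label") {
  if (length(value_columns) == 0) {
    stop_config("nothing to bind: no value columns")
  }
  if (is.null(p_columns)) p_columns <- rep(NA_character_, length(value_columns))
  if (length(p_columns) != length(value_columns)) {
    stop_config("p_columns must match value_columns in length (use NA for none)")
  }
  series <- tibble(
    name = as.character(value_columns),
    value_column = as.character(value_columns),
    p_column = as.character(p_columns)
  )
  used <- c(series$value_column, stats::na.omit(series$p_column))
  if (id_column %in% used) {
    stop_config("id column '", id_column, "' cannot also be a value/p column")
  }
  if (any(!is.na(series$p_column) & series$p_column == series$value_column)) {
    stop_config("a series' p column must differ from its value column")
  }
  match_attribute <- match.arg(
    match_attribute, c("label", "node_id", "xref_id", "xref_db")
  )
  structure(
    list(
      id_column = id_column, series = series,
      match_attribute = match_attribute
    ),
    class = "binding_spec"
  )
}

#' @export
print.binding_spec <- function(x, ...) {
  with_p <- sum(!is.na(x$series$p_column))
  cat(sprintf(
    "<binding_spec: id '%s', %d series (%d with p-values), match on %s>\n",
    x$id_column, nrow(x$series), with_p, x$match_attribute
  ))
  invisible(x)
}

#' Auto-detect the sample structure of a measurement table
#'
#' Applies the column-order rule: the first column holds identifiers, and the
#' remaining columns describe the samples. When the remaining column count is
#' even, consecutive pairs become (value, p-value) series; when it is odd,
#' every remaining column becomes a value-only series (the even pairing would
#' leave one column over, so the total value-only reading is the only
#' deterministic one). Series keep the table's left-to-right order and are
#' named after their value column.
#'
#' @param table A data frame, typically from [read_delimited_table()]. If the
#'   table carries an `id_column` attribute it is honored; otherwise the
#'   first column is the identifier.
#' @param match_attribute Passed through to [binding_spec()].
#' @return A [binding_spec()].
#' @examples
#' tbl <- read_delimited_table("id,fc_0h,p_0h,fc_2h,p_2h\nG1,1,0.1,2,0.2")
#' auto_bind(tbl)
#' @export
auto_bind <- function(table, match_attribute = "label") {
  cols <- names(table)
  idc <- attr(table, "id_column") %||% cols[1]
  rest <- setdiff(cols, idc)
  if (length(cols) < 2 || length(rest) == 0) {
    stop_config("nothing to bind: table needs an id column plus data columns")
  }
  if (length(rest) %% 2 == 0) {
    odd <- seq(1, length(rest), by = 2)
    binding_spec(idc, rest[odd], rest[odd + 1], match_attribute)
  } else {
    binding_spec(idc, rest, NULL, match_attribute)
  }
}

#' Match table identifiers to map nodes
#'
#' Performs an exact, case-sensitive string match between the table's
#' identifier column and the chosen attribute of each bindable (data) node.
#' No fuzzy matching and no identifier-system translation is attempted: the
#' identifiers in the data file must be written exactly as in the map.
#' Decoration nodes never match. A matched node contributes, per series, its
#' value and p-value; a missing value cell leaves the node without data for
#' that series (it will be rendered under the no-data policy).
#'
#' @param map A [network_map()].
#' @param table The measurement table.
#' @param spec A [binding_spec()]; defaults to [auto_bind()] of the table.
#' @param allow_duplicates Duplicated identifiers in the table are an error
#'   by default; with `TRUE`, the first occurrence wins and a warning counts
#'   the discarded rows.
#' @return An object of class `binding_result`: a list with
#'   * `data`: tibble with columns `series`, `node_id`, `value`, `p` — one
#'     row per series and per matched node with a present value;
#'   * `matched_node_ids`: ids of data nodes whose key matched an identifier;
#'   * `unmatched_identifiers`: distinct table identifiers with no node;
#'   * `spec`: the binding spec used.
#' @examples
#' fx <- make_pathway(n_nodes = 6, n_edges = 5, seed = 1)
#' tbl <- make_measurements(fx$map, k_series = 2, seed = 1)$table
#' match_identifiers(fx$map, tbl)
#' @export
match_identifiers <- function(map, table, spec = auto_bind(table),
                              allow_duplicates = FALSE) {
  stopifnot(inherits(map, "network_map"), inherits(spec, "binding_spec"))
  cols <- c(
    spec$id_column, spec$series$value_column,
    stats::na.omit(spec$series$p_column)
  )
  absent <- setdiff(cols, names(table))
  if (length(absent) > 0) {
    stop_config(
      "binding spec references missing column(s): ",
      paste(absent, collapse = ", ")
    )
  }

  ids <- as.character(table[[spec$id_column]])
  dup <- duplicated(ids)
  if (any(dup)) {
    if (!allow_duplicates) {
      stop(sprintf(
        "duplicate identifier %s (line %d)",
        ids[dup][1], which(dup)[1] + 1L
      ), call. = FALSE)
    }
    warning(sum(dup), " duplicated identifier row(s) discarded (first wins)",
      call. = FALSE
    )
    table <- table[!dup, ]
    ids <- ids[!dup]
  }

  data_nodes <- dplyr::filter(map$nodes, .data$kind == "data_node")
  key <- as.character(data_nodes[[spec$match_attribute]])
  row_of <- match(key, ids)
  matched_node_ids <- data_nodes$node_id[!is.na(row_of)]
  unmatched <- setdiff(unique(ids), key)

  long <- purrr::pmap(spec$series, function(name, value_column, p_column) {
    value <- table[[value_column]][row_of]
    p <- if (is.na(p_column)) rep(NA_real_, length(value)) else table[[p_column]][row_of]
    keep <- !is.na(row_of) & !is.na(value)
    tibble(
      series = name,
      node_id = data_nodes$node_id[keep],
      value = as.numeric(value[keep]),
      p = as.numeric(p[keep])
    )
  })
  long <- dplyr::bind_rows(long)
  bad_p <- !is.na(long$p) & (long$p < 0 | long$p > 1)
  if (any(bad_p)) {
    stop_config(
      "p-values must lie in [0, 1]; offending node(s): ",
      paste(utils::head(unique(long$node_id[bad_p]), 3), collapse = ", ")
    )
  }

  structure(
    list(
      data = long,
      matched_node_ids = matched_node_ids,
      unmatched_identifiers = unmatched,
      spec = spec
    ),
    class = "binding_result"
  )
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf(
    "<binding_result: %d matched node(s), %d unmatched identifier(s), %d series>\n",
    length(x$matched_node_ids), length(x$unmatched_identifiers),
    nrow(x$spec$series)
  ))
  invisible(x)
}
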