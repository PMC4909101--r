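run_config_defaults <- function() {
  list(
    network = NULL, network_format = "auto",
    data = NULL, separator = "auto", id_column = "first",
    match_attribute = "label",
    mode = "fold_change_gradient", cutoff = 0.05,
    up_color = "#00FF00", down_color = "#FF0000",
    neutral_color = "#FFFFFF", no_data_color = "#C0C0C0",
    no_data_policy = "show", value_max = "auto",
    n_cols = "auto", out = NULL,
    series = NULL, allow_duplicates = FALSE
  )
}

#' Assemble a run configuration
#'
#' Collects every knob of the end-to-end pipeline into one validated list.
#' Values can come from a YAML config file, with arguments given here taking
#' precedence over the file (so command-line flags override the file), over
#' the defaults.
#'
#' @param ... Named settings; see Details.
#' @param config_file Optional path to a YAML file holding the same names.
#' @details Recognized names: `network` (path), `network_format`
#'   (`auto`/`gpml`/`sif`/`graphml`), `data` (path), `separator`
#'   (`auto`/`comma`/`semicolon`/`tab`/`whitespace`), `id_column`,
#'   `match_attribute`, `mode` (`fold_change_gradient`/`p_value_cutoff`),
#'   `cutoff`, `up_color`, `down_color`, `neutral_color`, `no_data_color`,
#'   `no_data_policy` (`show`/`grey`/`hide`), `value_max`, `n_cols`, `out`
#'   (SVG path or `NULL`), `series` (manual binding: character vector of
#'   `"value"` or `"value:p"` column pairs; `NULL` = auto-detect),
#'   `allow_duplicates`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(..., config_file = NULL) {
  defaults <- run_config_defaults()
  from_file <- if (!is.null(config_file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for config files", call. = FALSE)
    }
    yaml::read_yaml(config_file)
  } else {
    list()
  }
  given <- list(...)
  unknown <- setdiff(c(names(from_file), names(given)), names(defaults))
  if (length(unknown) > 0) {
    stop_config("unknown setting(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), given)

  if (is.null(cfg$network) || !nzchar(cfg$network)) {
    stop_config("network path must be given")
  }
  if (is.null(cfg$data) || !nzchar(cfg$data)) {
    stop_config("data path must be given")
  }
  cfg$network_format <- match.arg(cfg$network_format, c("auto", "gpml", "sif", "graphml"))
  cfg$separator <- match.arg(cfg$separator, c("auto", "comma", "semicolon", "tab", "whitespace"))
  cfg$mode <- match.arg(cfg$mode, c("fold_change_gradient", "p_value_cutoff"))
  cfg$no_data_policy <- match.arg(cfg$no_data_policy, c("show", "grey", "hide"))
  structure(cfg, class = "run_config")
}

config_style <- function(cfg) {
  visual_style(
    up_color = cfg$up_color, down_color = cfg$down_color,
    neutral_color = cfg$neutral_color, no_data_color = cfg$no_data_color,
    mode = cfg$mode, cutoff = cfg$cutoff,
    no_data_policy = cfg$no_data_policy, value_max = cfg$value_max
  )
}

sniff_network_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gpml", "sif", "graphml")) {
    return(ext)
  }
  first <- tryCatch(
    xml2::xml_name(xml2::read_xml(path)),
    error = function(e) NA_character_
  )
  if (identical(first, "Pathway")) {
    return("gpml")
  }
  if (identical(first, "graphml")) {
    return("graphml")
  }
  if (is.na(first)) {
    return("sif")
  }
  stop("cannot determine network format of ", path, call. = FALSE)
}

parse_series_spec <- function(series, id_column, match_attribute) {
  pairs <- stringr::str_split(series, stringr::fixed(":"))
  value_cols <- purrr::map_chr(pairs, 1)
  p_cols <- purrr::map_chr(pairs, function(x) {
    if (length(x) > 1) x[2] else NA_character_
  })
  binding_spec(id_column, value_cols, p_cols, match_attribute)
}

#' Run the whole pipeline: files in, small-multiples SVG out
#'
#' Reads the network/pathway map and the measurement table, binds the table
#' to the map, styles and replicates it per sample, renders the SVG, and (if
#' `out` is set) writes it. Progress is logged one line at a time via
#' [message()] (which prints to stderr): the separator used, the detected
#' series, the matched/unmatched identifier counts and the panel count.
#' Unmatched identifiers are reported as a warning, never an error.
#'
#' @param config A [run_config()].
#' @return The `rendered_document`, invisibly.
#' @export
render_small_multiples <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fmt <- config$network_format
  if (fmt == "auto") fmt <- sniff_network_format(config$network)
  if (!file.exists(config$network)) {
    stop("network file not found: ", config$network, call. = FALSE)
  }
  if (!file.exists(config$data)) {
    stop("data file not found: ", config$data, call. = FALSE)
  }
  map <- if (fmt == "gpml") {
    read_gpml(config$network)
  } else {
    read_simple_network(config$network, fmt)
  }
  message(sprintf(
    "network: format=%s nodes=%d edges=%d", fmt,
    nrow(map$nodes), nrow(map$edges)
  ))

  table <- read_delimited_table(config$data, config$separator, config$id_column)
  message(sprintf(
    "data: separator=%s rows=%d columns=%d",
    attr(table, "separator"), nrow(table), ncol(table)
  ))

  spec <- if (is.null(config$series)) {
    auto_bind(table, config$match_attribute)
  } else {
    parse_series_spec(
      config$series,
      attr(table, "id_column"), config$match_attribute
    )
  }
  message(sprintf(
    "series: %s", paste(
      sprintf(
        "%s%s", spec$series$name,
        ifelse(is.na(spec$series$p_column), "", sprintf(" (p: %s)", spec$series$p_column))
      ),
      collapse = ", "
    )
  ))

  binding <- match_identifiers(map, table, spec, config$allow_duplicates)
  message(sprintf(
    "binding: matched=%d unmatched=%d",
    length(binding$matched_node_ids), length(binding$unmatched_identifiers)
  ))
  if (length(binding$unmatched_identifiers) > 0) {
    warning(
      length(binding$unmatched_identifiers),
      " identifier(s) matched no node: ",
      paste(utils::head(binding$unmatched_identifiers, 5), collapse = ", "),
      if (length(binding$unmatched_identifiers) > 5) ", ..." else "",
      call. = FALSE
    )
  }

  style <- config_style(config)
  panels <- build_panels(map, binding, style)
  doc <- render_svg(panels, grid_spec(n_cols = config$n_cols))
  message(sprintf(
    "render: %d panels, %g x %g", length(panels$panels), doc$width, doc$height
  ))

  if (!is.null(config$out)) {
    write_svg(doc, config$out)
    message("wrote ", config$out)
  }
  invisible(doc)
}
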