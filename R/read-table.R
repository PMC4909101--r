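SEPARATORS <- c(
  tab = "\t",
  comma = ",",
  semicolon = ";",
  whitespace = "[[:space:]]+"
)

split_fields <- function(lines, separator) {
  if (separator == "whitespace") {
    stringr::str_split(stringr::str_trim(lines), SEPARATORS[["whitespace"]])
  } else {
    stringr::str_split(lines, stringr::fixed(SEPARATORS[[separator]]))
  }
}

#' Detect the field separator of a delimited text table
#'
#' Inspects up to the first 10 non-empty lines and picks, among tab, comma,
#' semicolon and runs-of-whitespace, the separator that yields the most
#' columns while giving every sampled line the same column count. Ties are
#' broken by the precedence tab > comma > semicolon > whitespace.
#'
#' @param text A single string (possibly multi-line) or a character vector of
#'   lines.
#' @return One of `"tab"`, `"comma"`, `"semicolon"`, `"whitespace"`.
#' @examples
#' detect_separator("id,fc,p\nG1,2.0,0.01")
#' detect_separator("id\tfc\nG1\t2.0")
#' @export
detect_separator <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\r\n|\n|\r")[[1]]
  lines <- utils::head(text[nzchar(trimws(text))], 10L)
  if (length(lines) == 0) stop("undetectable separator: no content", call. = FALSE)

  best <- NULL
  best_n <- 1L
  for (candidate in c("tab", "comma", "semicolon", "whitespace")) {
    counts <- lengths(split_fields(lines, candidate))
    if (length(unique(counts)) == 1L && counts[1] > best_n) {
      best <- candidate
      best_n <- counts[1]
    }
  }
  if (is.null(best)) {
    stop("undetectable separator: no candidate yields >= 2 consistent columns",
      call. = FALSE
    )
  }
  best
}

#' Read a delimited measurement table
#'
#' Reads a text table whose first line is a header, with an identifier column
#' and numeric value (and optionally p-value) columns. Accepts comma,
#' semicolon, tab or arbitrary-whitespace separated values; `separator =
#' "auto"` sniffs the separator with [detect_separator()]. Numeric cells are
#' parsed as decimal floats; empty or non-numeric cells in value columns
#' become missing (`NA`). The decimal mark is always the point — locale
#' comma-decimals are not supported (a semicolon-separated file with comma
#' decimals would be ambiguous).
#'
#' @param path Path to the file (UTF-8, LF or CRLF line endings), or a
#'   literal multi-line string containing the table text.
#' @param separator `"auto"` or one of `"comma"`, `"semicolon"`, `"tab"`,
#'   `"whitespace"`.
#' @param id_column `"first"` (default) or the header name of the identifier
#'   column. The identifier column is kept as character; all other columns
#'   are parsed numerically.
#' @return A tibble with one column per header field, carrying the attribute
#'   `id_column` (the resolved identifier column name) and `separator`.
#' @examples
#' tbl <- read_delimited_table("id,fc,p\nG1,2.0,0.01\nG2,-1.5,0.2")
#' tbl
#' attr(tbl, "id_column")
#' @export
read_delimited_table <- function(path, separator = "auto", id_column = "first") {
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    src <- path
  } else {
    lines <- strsplit(path, "\r\n|\n|\r")[[1]]
    src <- "<text>"
  }
  # strip a UTF-8 byte-order mark, if any
  if (length(lines) > 0) lines[1] <- sub("\ufeff", "", lines[1], fixed = TRUE)
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) stop("empty file: ", src, call. = FALSE)

  separator <- match.arg(separator, c("auto", names(SEPARATORS)))
  if (separator == "auto") separator <- detect_separator(lines)

  fields <- split_fields(lines, separator)
  header <- fields[[1]]
  n_col <- length(header)
  if (n_col < 2) {
    stop("header of ", src, " has fewer than 2 columns under separator '",
      separator, "'",
      call. = FALSE
    )
  }
  if (any(!nzchar(header)) || anyDuplicated(header)) {
    stop("header of ", src, " must have unique, non-empty column names",
      call. = FALSE
    )
  }
  if (length(fields) == 1L) stop("header-only file: ", src, call. = FALSE)

  widths <- lengths(fields)
  bad <- which(widths != n_col)[1]
  if (!is.na(bad)) {
    stop(sprintf(
      "parse error in %s: line %d has %d fields, expected %d",
      src, bad, widths[bad], n_col
    ), call. = FALSE)
  }

  cells <- do.call(rbind, fields[-1])
  colnames(cells) <- header

  if (identical(id_column, "first")) id_column <- header[1]
  if (!id_column %in% header) {
    stop("id column '", id_column, "' not found in header of ", src,
      call. = FALSE
    )
  }

  out <- purrr::map(seq_len(n_col), function(j) {
    col <- cells[, j]
    if (header[j] == id_column) {
      return(col)
    }
    suppressWarnings(as.numeric(ifelse(nzchar(trimws(col)), col, NA)))
  })
  names(out) <- header
  out <- as_tibble(out)

  blank_id <- which(!nzchar(trimws(out[[id_column]])))
  if (length(blank_id) > 0) {
    stop(sprintf(
      "parse error in %s: empty identifier at line %d",
      src, blank_id[1] + 1L
    ), call. = FALSE)
  }

  attr(out, "id_column") <- id_column
  attr(out, "separator") <- separator
  out
}
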