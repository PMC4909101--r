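#' @importFrom rlang %||%
#' @importFrom tibble tibble as_tibble
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Minimal XML text escaping for attribute and text content.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Deterministic numeric formatting for XML/SVG output: plain decimal,
# no scientific notation, trailing zeros trimmed.
fmt_num <- function(x) {
  s <- formatC(x, format = "f", digits = 4)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

# Configuration/validation errors carry their own class so callers (notably
# the CLI) can distinguish them from I/O and parse failures.
stop_config <- function(...) {
  rlang::abort(paste0(...), class = "pathpanels_config_error")
}

is_hex_color <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^#[0-9A-Fa-f]{6}$", x)
}
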