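#' Generate a synthetic pathway map
#'
#' Builds a reproducible map for testing and demonstration: `n_nodes` data
#' nodes labelled `G1...Gn` on a deterministic grid, `n_edges` distinct
#' node pairs drawn with the given seed, and `n_decorations` decorative
#' labels placed beneath the grid. Also returns the map serialized as GPML
#' text, which re-reads (via [read_gpml()]) to an identical map.
#'
#' @param n_nodes Number of data nodes (>= 1).
#' @param n_edges Number of edges, at most `n_nodes * (n_nodes - 1) / 2`.
#' @param n_decorations Number of decoration (label) nodes.
#' @param seed Integer seed; the same seed gives byte-identical GPML.
#' @return A list with `map` (a [network_map()]) and `gpml` (character).
#' @examples
#' fx <- make_pathway(n_nodes = 6, n_edges = 5, seed = 42)
#' fx$map
#' @export
make_pathway <- function(n_nodes, n_edges = n_nodes, n_decorations = 0,
                         seed = 1L) {
  stopifnot(n_nodes >= 1, n_edges >= 0, n_decorations >= 0)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    stop("n_edges = ", n_edges, " infeasible for ", n_nodes,
      " nodes (max ", max_edges, ")",
      call. = FALSE
    )
  }

  node_w <- 90
  node_h <- 30
  sp_x <- 130
  sp_y <- 60
  n_col <- ceiling(sqrt(n_nodes))
  idx <- seq_len(n_nodes) - 1L
  nodes <- tibble(
    node_id = sprintf("n%d", seq_len(n_nodes)),
    label = sprintf("G%d", seq_len(n_nodes)),
    kind = "data_node",
    x = node_w / 2 + (idx %% n_col) * sp_x,
    y = node_h / 2 + (idx %/% n_col) * sp_y,
    width = node_w, height = node_h,
    xref_db = "Synthetic",
    xref_id = sprintf("SYN%04d", seq_len(n_nodes))
  )

  if (n_decorations > 0) {
    deco_y <- max(nodes$y) + node_h / 2 + 40
    nodes <- dplyr::bind_rows(nodes, tibble(
      node_id = sprintf("d%d", seq_len(n_decorations)),
      label = sprintf("annotation %d", seq_len(n_decorations)),
      kind = "decoration",
      x = 60 + (seq_len(n_decorations) - 1) * 160,
      y = deco_y,
      width = 120, height = 20,
      xref_db = NA_character_, xref_id = NA_character_
    ))
  }

  edges <- if (n_edges > 0) {
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    pick <- local_seed(seed, sample.int(nrow(pairs), n_edges))
    tibble(
      source = sprintf("n%d", pairs[pick, "row"]),
      target = sprintf("n%d", pairs[pick, "col"])
    )
  } else {
    NULL
  }

  map <- network_map(sprintf("synthetic pathway (seed %d)", seed), nodes, edges)
  list(map = map, gpml = write_gpml(map))
}

#' Generate a synthetic measurement table for a map
#'
#' Emulates the shape of a time-course expression experiment: one row per
#' data node of the map (a seeded fraction of identifiers is replaced by
#' novel ones that match nothing, emulating probes absent from the map),
#' with one signed value column per series (zero-mean normal draws, think
#' log2 fold changes) and, optionally, one p-value column per series. A
#' seeded `frac_significant` subset of rows gets p-values drawn uniformly
#' from \[0, 0.025\] (clearly below the 0.05 reference cutoff) and the rest
#' from (0.05, 1\].
#'
#' The defaults mirror a 5-point time course (series `0h, 2h, 12h, 24h,
#' 72h` with p-value columns), the shape used throughout the package's
#' examples and tests.
#'
#' @param map A [network_map()] with at least one data node.
#' @param k_series Number of sample series.
#' @param with_p Add a p-value column per series?
#' @param frac_significant Fraction of rows given sub-cutoff p-values.
#' @param frac_unmatched Fraction of identifiers replaced by novel ones.
#' @param value_sd Standard deviation of the value draws.
#' @param seed Integer seed; the same seed gives byte-identical CSV.
#' @param series_names Optional series names; defaults to
#'   `0h/2h/12h/24h/72h` when `k_series` is 5, else `s1...sk`.
#' @return A list with `table` (a tibble, `id_column` attribute set) and
#'   `csv` (the same table as comma-separated text).
#' @examples
#' fx <- make_pathway(n_nodes = 6, n_edges = 5, seed = 1)
#' mm <- make_measurements(fx$map, seed = 1)
#' names(mm$table)
#' @export
make_measurements <- function(map, k_series = 5, with_p = TRUE,
                              frac_significant = 0.3, frac_unmatched = 0.1,
                              value_sd = 1, seed = 1L, series_names = NULL) {
  stopifnot(
    inherits(map, "network_map"),
    k_series >= 1,
    frac_significant >= 0, frac_significant <= 1,
    frac_unmatched >= 0, frac_unmatched <= 1,
    value_sd > 0
  )
  ids <- map$nodes$label[map$nodes$kind == "data_node"]
  n <- length(ids)
  if (n == 0) stop("map has no data nodes", call. = FALSE)

  if (is.null(series_names)) {
    series_names <- if (k_series == 5) {
      c("0h", "2h", "12h", "24h", "72h")
    } else {
      sprintf("s%d", seq_len(k_series))
    }
  }
  stopifnot(length(series_names) == k_series)

  cutoff_ref <- 0.05
  tab <- local_seed(seed, {
    n_unmatched <- round(frac_unmatched * n)
    if (n_unmatched > 0) {
      swap <- sample.int(n, n_unmatched)
      ids[swap] <- sprintf("U%d", seq_len(n_unmatched))
    }
    cols <- list(id = ids)
    for (s in series_names) {
      cols[[s]] <- stats::rnorm(n, mean = 0, sd = value_sd)
      if (with_p) {
        p <- stats::runif(n, min = cutoff_ref, max = 1)
        n_sig <- round(frac_significant * n)
        if (n_sig > 0) {
          sig <- sample.int(n, n_sig)
          p[sig] <- stats::runif(n_sig, min = 0, max = cutoff_ref / 2)
        }
        cols[[paste0("p_", s)]] <- p
      }
    }
    as_tibble(cols)
  })
  attr(tab, "id_column") <- "id"

  # %.17g round-trips doubles exactly, so the CSV parses back to this table
  cells <- purrr::map(tab, function(col) {
    if (is.character(col)) col else sprintf("%.17g", col)
  })
  lines <- c(
    paste(names(tab), collapse = ","),
    do.call(paste, c(cells, sep = ","))
  )
  list(table = tab, csv = paste0(paste(lines, collapse = "\n"), "\n"))
}
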