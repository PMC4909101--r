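test_that("detect_separator picks the consistent separator and breaks ties by precedence", {
  expect_identical(detect_separator("a,b,c\nd,e,f"), "comma")
  expect_identical(detect_separator("a\tb\nc\td"), "tab")
  expect_identical(detect_separator("a;b;c\nd;e;f"), "semicolon")
  expect_identical(detect_separator("a b c\nd e f"), "whitespace")
  # tab outranks whitespace although both split a tab-separated line
  expect_identical(detect_separator("a\tb\tc\nd\te\tf"), "tab")
  # the separator giving more columns wins over one giving fewer
  expect_identical(detect_separator("a,b;x,c\nd,e,f"), "comma")
})

test_that("detect_separator refuses input without >= 2 consistent columns", {
  expect_error(detect_separator("abc\ndef"), "undetectable separator")
  expect_error(detect_separator(""), "undetectable separator")
  # inconsistent column counts under every candidate
  expect_error(detect_separator("a,b\nc,d,e\nf"), "undetectable separator")
})

test_that("read_delimited_table parses values, missing cells and whitespace runs", {
  tbl <- read_delimited_table("id,fc,p\nG1,2.0,0.01")
  expect_identical(names(tbl), c("id", "fc", "p"))
  expect_identical(nrow(tbl), 1L)
  expect_identical(tbl$fc, 2.0)
  expect_identical(attr(tbl, "id_column"), "id")

  # runs of mixed whitespace collapse into single field breaks
  tbl2 <- read_delimited_table("id fc p\nG1  2.0\t0.01", separator = "whitespace")
  expect_identical(unlist(tbl2[1, ], use.names = FALSE), c("G1", "2", "0.01"))

  # empty and non-numeric value cells become NA; identifiers stay character
  tbl3 <- read_delimited_table("id,fc,p\nG1,,n.d.\nG2,-1.5,0.2")
  expect_true(is.na(tbl3$fc[1]) && is.na(tbl3$p[1]))
  expect_identical(tbl3$id, c("G1", "G2"))
})

test_that("read_delimited_table rejects degenerate files with line information", {
  expect_error(
    read_delimited_table("id,fc,p\nG1,2.0", separator = "comma"),
    "line 2"
  )
  expect_error(read_delimited_table("id,fc,p\nG1,1,1\nG2,3", separator = "comma"), "line 3")
  expect_error(read_delimited_table("id,fc,p"), "header-only")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), f)
  expect_error(read_delimited_table(f), "empty file")
  expect_error(read_delimited_table("id,fc\n,2.0"), "empty identifier at line 2")
})

test_that("the same logical table parses identically under all four separators", {
  fx <- make_pathway(n_nodes = 8, n_edges = 6, seed = 3)
  tab <- make_measurements(fx$map, k_series = 3, seed = 3)$table
  render <- function(sep) {
    cells <- lapply(tab, function(col) if (is.character(col)) col else sprintf("%.17g", col))
    paste(c(
      paste(names(tab), collapse = sep),
      do.call(paste, c(cells, sep = sep))
    ), collapse = "\n")
  }
  ref <- tbl_cols(read_delimited_table(render(","), separator = "comma"))
  for (sep in list(c(";", "semicolon"), c("\t", "tab"), c(" ", "whitespace"))) {
    got <- tbl_cols(read_delimited_table(render(sep[1]), separator = sep[2]))
    expect_identical(tbl_cols(got), tbl_cols(ref))
    # and the sniffer finds each encoding on its own
    expect_identical(
      tbl_cols(read_delimited_table(render(sep[1]))),
      tbl_cols(ref)
    )
  }
})

test_that("read_gpml builds data nodes, decorations and edges from GPML", {
  gpml <- toy_gpml(paste0(
    gpml_data_node("a", "G1", x = 50, y = 20),
    gpml_data_node("b", "G2", x = 200, y = 20),
    gpml_interaction("a", "b")
  ))
  map <- read_gpml(gpml)
  expect_s3_class(map, "network_map")
  expect_identical(sum(map$nodes$kind == "data_node"), 2L)
  expect_identical(nrow(map$edges), 1L)
  expect_identical(map$edges$source, "a")

  # Labels become decorations, never edges
  gpml2 <- toy_gpml(paste0(
    gpml_data_node("a", "G1"),
    '<Label TextLabel="note" GraphId="l1"><Graphics CenterX="50" CenterY="80" Width="60" Height="15"/></Label>'
  ))
  map2 <- read_gpml(gpml2)
  expect_identical(map2$nodes$kind, c("data_node", "decoration"))
  expect_identical(nrow(map2$edges), 0L)
})

test_that("read_gpml drops unresolvable interactions with a warning but keeps the map", {
  gpml <- toy_gpml(paste0(
    gpml_data_node("a", "G1"),
    gpml_data_node("b", "G2", x = 200),
    gpml_interaction("a", "ghost")
  ))
  expect_warning(map <- read_gpml(gpml), "unresolvable")
  expect_identical(nrow(map$edges), 0L)
  expect_identical(nrow(map$nodes), 2L)
})

test_that("read_gpml rejects malformed or foreign input", {
  expect_error(read_gpml("this is not xml <"), "not well-formed")
  expect_error(
    read_gpml('<Pathway Name="x"><DataNode/></Pathway>'),
    "namespace"
  )
  no_graphics <- toy_gpml('<DataNode TextLabel="G1" GraphId="a"></DataNode>')
  expect_error(read_gpml(no_graphics), "no Graphics")
})

test_that("GPML write -> read reproduces counts, labels and coordinates exactly", {
  for (seed in 1:5) {
    fx <- make_pathway(
      n_nodes = 5 + seed, n_edges = 4 + seed,
      n_decorations = seed %% 3, seed = seed
    )
    back <- read_gpml(write_gpml(fx$map))
    expect_identical(nrow(back$nodes), nrow(fx$map$nodes))
    expect_identical(nrow(back$edges), nrow(fx$map$edges))
    expect_identical(back$nodes$label, fx$map$nodes$label)
    expect_identical(back$nodes$x, fx$map$nodes$x)
    expect_identical(back$nodes$y, fx$map$nodes$y)
  }
})

test_that("read_simple_network parses SIF with deterministic circular coordinates", {
  map <- read_simple_network("A pp B\nB pp C", "sif")
  expect_identical(nrow(map$nodes), 3L)
  expect_identical(nrow(map$edges), 2L)
  expect_true(all(map$nodes$kind == "data_node"))

  again <- read_simple_network("A pp B\nB pp C", "sif")
  expect_identical(again$nodes$x, map$nodes$x)
  expect_identical(again$nodes$y, map$nodes$y)

  isolated <- read_simple_network("A", "sif")
  expect_identical(nrow(isolated$nodes), 1L)
  expect_identical(nrow(isolated$edges), 0L)

  # one source, one relation, several targets on a single line
  multi <- read_simple_network("A pp B C D", "sif")
  expect_identical(nrow(multi$edges), 3L)
  expect_error(read_simple_network("A pp", "sif"), "malformed SIF line 1")
})

test_that("read_simple_network parses GraphML, honoring positions when present", {
  gml <- paste0(
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="d0" attr.name="x" for="node"/><key id="d1" attr.name="y" for="node"/>',
    '<graph edgedefault="undirected">',
    '<node id="A"><data key="d0">10</data><data key="d1">30</data></node>',
    '<node id="B"><data key="d0">110</data><data key="d1">30</data></node>',
    '<edge source="A" target="B"/>',
    "</graph></graphml>"
  )
  map <- read_simple_network(gml, "graphml")
  expect_identical(nrow(map$nodes), 2L)
  expect_identical(nrow(map$edges), 1L)
  # positions honored up to the uniform shift that puts the bbox at (0,0)
  expect_identical(diff(map$nodes$x), 100)

  no_pos <- '<graphml><graph><node id="A"/><node id="B"/><edge source="A" target="B"/></graph></graphml>'
  m1 <- read_simple_network(no_pos, "graphml")
  m2 <- read_simple_network(no_pos, "graphml")
  expect_identical(m1$nodes$x, m2$nodes$x)
  expect_error(read_simple_network("<graphml><graph>", "graphml"), "not well-formed")
})

test_that("every edge of a returned map resolves both endpoints", {
  for (seed in 1:10) {
    fx <- make_pathway(n_nodes = 4 + seed, n_edges = 2 * seed, seed = seed)
    map <- read_gpml(fx$gpml)
    expect_true(all(map$edges$source %in% map$nodes$node_id))
    expect_true(all(map$edges$target %in% map$nodes$node_id))
  }
})
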