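Package: pathpanels
Title: Small-Multiple Visualization of Omics Data on Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects per-sample measurement data (values such as log2 fold
    changes, with optional p-values) onto a pathway or network map as "small
    multiples": one colored copy of the map per sample, composed into a single
    SVG document. Reads pathway maps in GPML (WikiPathways/PathVisio dialect)
    and plain networks in SIF or GraphML, parses delimited measurement tables
    with separator auto-detection, auto-binds value/p-value column pairs to
    map nodes by identifier, and styles nodes either by a two-color fold-change
    gradient or by direction-at-significance under a p-value cutoff, with
    configurable handling of nodes that carry no data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
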