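# Shared helpers for inspecting rendered SVG output with a strict XML parser.

svg_xml <- function(doc) xml2::read_xml(doc$svg_text)

svg_panel_groups <- function(doc) {
  xml2::xml_find_all(svg_xml(doc), "//*[local-name()='g' and @class='panel']")
}

group_rects <- function(g) xml2::xml_find_all(g, ".//*[local-name()='rect']")

group_lines <- function(g) xml2::xml_find_all(g, ".//*[local-name()='line']")

rect_fills <- function(g) xml2::xml_attr(group_rects(g), "fill")

# A small GPML document assembled by hand, independent of write_gpml().
toy_gpml <- function(body, name = "toy") {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="', name, '">\n',
    body,
    "\n</Pathway>"
  )
}

gpml_data_node <- function(id, label, x = 50, y = 20, w = 80, h = 25) {
  sprintf(
    '<DataNode TextLabel="%s" GraphId="%s"><Graphics CenterX="%s" CenterY="%s" Width="%s" Height="%s"/></DataNode>',
    label, id, x, y, w, h
  )
}

gpml_interaction <- function(from, to) {
  sprintf(
    '<Interaction><Graphics><Point GraphRef="%s" X="0" Y="0"/><Point GraphRef="%s" X="1" Y="1"/></Graphics></Interaction>',
    from, to
  )
}

# The settings of the demonstration rendering: grey out unbound nodes,
# significance coloring at cutoff 0.1.
use_case_style <- function() {
  visual_style(mode = "p_value_cutoff", cutoff = 0.1, no_data_policy = "grey")
}

# Columns of a table as a bare named list (bookkeeping attributes dropped),
# for comparing parses across separators.
tbl_cols <- function(x) {
  out <- as.list(x)
  attributes(out) <- list(names = names(out))
  out
}
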