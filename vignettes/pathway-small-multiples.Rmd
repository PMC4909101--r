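---
title: "Small multiples of pathway maps: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small multiples of pathway maps: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpanels)
```

## What the package computes

Given a pathway or network map and a table of per-sample measurements,
`pathpanels` renders the map once per sample with nodes colored from that
sample's values — a *small multiples* figure. The point of small multiples
is comparative reading: every panel is the same picture except for color, so
differences between samples (time points, tissues, treatments) are read
directly, without chasing node positions across layouts. That constraint
drives most of the design below: one template geometry, one shared color
scale, deterministic output.

## The data model

A **map** is a node table plus an edge table. Nodes carry canvas geometry
(center `x`/`y`, `width`, `height`; origin top-left, y growing downward,
exactly as in SVG) and a `kind`: `data_node`s are biological entities
(genes, proteins, metabolites) that can receive measurements; `decoration`s
are labels and shapes that exist only visually. Edges are node-id pairs and
must resolve within the map. On import, coordinates are kept as-is apart
from one uniform translation that puts the bounding box at (0, 0), so GPML
geometry survives a write/read round trip exactly.

A **measurement table** is a header-first delimited text file: an identifier
column, then numeric columns. Sample structure is detected by column order:
with an even number of non-identifier columns, consecutive pairs become
(value, p-value) series; with an odd number, every column becomes a
value-only series. The even/odd rule is the only total, deterministic
reading — with an odd residue any pairing would have to guess which column
lacks a partner, so we refuse to guess. A manual `binding_spec()` covers
tables the rule cannot express.

Identifier matching is exact and case-sensitive against a chosen node
attribute (the label by default). We deliberately do no fuzzy matching and
no identifier-system translation: silent approximate matches corrupt
figures in ways that are hard to spot, whereas an unmatched-identifier
warning is actionable. Duplicate identifiers are an error by default
(first-wins is available behind an explicit flag) for the same reason.

## Coloring

Two modes, chosen per run:

**Fold-change gradient.** A value $v$ maps to a color by piecewise-linear
interpolation per RGB channel between three anchors: `down_color` at
$-v_{\max}$, `neutral_color` at $0$, `up_color` at $+v_{\max}$, clamped
outside. Channels are rounded half-up. The linear-RGB law with a white
midpoint is the simplest reproducible choice consistent with "white means no
change"; perceptually uniform ramps are out of scope and would change every
rendered byte for a marginal gain at these few-color extremes. With
`value_max = "auto"` (the default), $v_{\max}$ is the largest $|v|$ over
**all** series jointly — per-panel scaling would make identical colors mean
different magnitudes in different panels, defeating the small-multiples
premise.

**Significance cutoff.** A node is colored by the *sign* of its value only
when $p \le \text{cutoff}$, else neutral; a significant value of exactly 0
has no direction and stays neutral. The cutoff is inclusive, is a free
float in (0, 1], and the four conventional presets (0.001, 0.01, 0.05, 0.1)
are exposed via `cutoff_presets()`. Defaults: up = green `#00FF00`, down =
red `#FF0000`, the standard convention for up-/down-regulated genes;
neutral white and no-data grey `#C0C0C0` are our choices (the convention
fixes only up/down) and are configurable.

**No-data policy.** Nodes without a bound value are shown with their neutral
fill (default), greyed, or hidden; hiding a node removes its incident edges
too, since a dangling edge would imply a relation to nothing. Decorations
are always greyed and never hidden — they are part of the template, not of
the data. Two corner cases we had to decide: a value column *without* a
p-value partner under significance mode is a configuration error (refusing
beats guessing a p-value semantics); a bound node whose p-value cell is
*missing* under significance mode is treated as no-data for that series,
the same as a missing value cell — there is no honest way to classify it.

## Rendering

Panels are placed row-major in a grid; `n_cols = "auto"` uses
$\lceil\sqrt{k}\rceil$ columns, the near-square arrangement. Every node is
drawn as a rounded rectangle at its template position translated by the
panel offset, so a node occupies the identical within-panel position in
every panel; only fill and visibility vary. Edges are straight lines
between node centers, clipped at the node borders; GPML waypoint and anchor
geometry is ignored — a headless renderer needs one deterministic routing
rule, and straight center-to-center lines are it. Panel titles are the
series names (value-column headers), a convention rather than a standard.
Text uses a single generic `sans-serif` family with no font embedding,
keeping the SVG portable and diffable. The output is deterministic to the
byte for identical inputs (fixed number formatting, no timestamps), which
makes figures version-controllable and regressions diffable.

The legend (up / down / no change / no data swatches) is a documented
extension: comparative figures are unreadable without one, so we append a
single legend group after the panels.

## The synthetic study

The fixture generator emulates the shape of a germination time-course
expression experiment: five series named `0h, 2h, 12h, 24h, 72h` with
p-value columns, over a map of ~30 gene nodes plus a few decorations —
roughly the size of a central-metabolism pathway diagram. Defaults chosen
once: `frac_significant = 0.3` (significant p-values drawn uniformly on
$[0, 0.025]$, the rest on $(0.05, 1]$, so the 0.05 reference cutoff
separates them cleanly), `frac_unmatched = 0.1` (a realistic share of
probes absent from any hand-drawn map), values from a zero-mean normal with
`value_sd = 1` on the log2 scale. Everything is seeded: the same seed gives
byte-identical GPML and CSV.

What the generator does *not* emulate: real microarray/RNA-seq noise
structure (correlated probes, intensity-dependent variance), multi-probe
genes needing aggregation, identifier aliasing across databases, and the
dense decoration/anchor geometry of curated WikiPathways diagrams. Tests
passing on these fixtures therefore demonstrate the mechanics — parsing,
binding bookkeeping, color law, panel composition — not robustness to messy
real-world annotation.

## Problem sizes used in the test suite

The suite runs maps of 4–30 nodes, 1–10 series, and repeats property checks
over 5–100 seeds (100 for the edge-hiding invariant, 1 000 random draws for
the gradient-oracle comparison, 30 seeds for the significant-fraction
convergence check). These sizes are where the properties are already fully
exercised — every code path in binding and rendering triggers at a handful
of nodes — while keeping the default test run fast enough to be part of
every development cycle.

## Numerical and degenerate-input choices

* Decimal points only in tables; locale comma-decimals are rejected by
  construction (a semicolon-separated file with comma decimals is
  ambiguous). Documented limitation.
* Separator auto-detection samples up to 10 lines and requires a consistent
  column count of at least 2; ties break tab > comma > semicolon >
  whitespace, preferring the more specific separator.
* Empty cells and non-numeric tokens in value columns become missing values
  rather than errors — tables exported from spreadsheets routinely contain
  `n.d.` and blanks.
* Channel rounding is half-up (`floor(x + 0.5)`), not banker's rounding, so
  the documented midpoint colors (e.g. `#80FF80` at $v_{\max}/2$) are exact.
* An all-missing binding under `value_max = "auto"` falls back to
  $v_{\max} = 1$; the value never matters (no node has data) but keeps the
  style total.
* GPML `Group` containers are flattened — member nodes are kept, the
  container ignored — because data binds to leaf entities.
* Maps without coordinates (SIF, GraphML without position keys) get a
  deterministic circular layout ordered by first appearance, radius
  proportional to node count; no force-directed layout, which would be
  non-deterministic or need tuning.

## Known limitations

No identifier translation (BridgeDb-style), no many-to-one probe
aggregation, no continuous p-value gradient, no node shape fidelity (all
nodes render as rounded rectangles), no PNG/PDF export, no live pathway
downloads. Each is either out of scope for a headless renderer or a
deliberate refusal documented above.

## A complete run

```{r example, fig.width = 7, fig.height = 4}
fx  <- make_pathway(n_nodes = 12, n_edges = 14, n_decorations = 1, seed = 3)
tbl <- read_delimited_table(make_measurements(fx$map, seed = 3)$csv)

binding <- match_identifiers(fx$map, tbl)
glance(binding)

style  <- visual_style(mode = "p_value_cutoff", cutoff = 0.1,
                       no_data_policy = "grey")
panels <- build_panels(fx$map, binding, style)
autoplot(panels)
```

```{r svg}
doc <- render_svg(panels)
doc
```
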