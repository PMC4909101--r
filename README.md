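# pathpanels

Small-multiple visualization of per-sample omics measurements on pathway and
network maps.

## The problem

Coloring a pathway diagram by expression works well for one sample, but a
time course or a panel of tissues needs one picture per sample that can be
compared at a glance. `pathpanels` builds *small multiples*: it replicates a
pathway or network map once per sample/experiment, colors each copy's nodes
from that sample's measurements, and composes the copies into a single SVG
figure with a shared color scale and legend. It is a headless library plus a
thin command-line wrapper, aimed at people who have a pathway map (GPML from
WikiPathways/PathVisio, or a plain SIF/GraphML network) and a delimited table
of values — typically log2 fold changes with p-values — and want a
publication-quality comparative figure without a GUI.

## The method

The pipeline has four stages, each an exported function:

1. **Map import** — `read_gpml()` parses GPML `DataNode`s (bindable
   entities with canvas geometry and Xrefs) and `Label`/`Shape` decorations;
   `read_simple_network()` reads SIF or GraphML, laying out coordinate-free
   networks deterministically on a circle.
2. **Data import and binding** — `read_delimited_table()` reads
   comma/semicolon/tab/whitespace-separated tables (separator auto-detected);
   `auto_bind()` applies the column-order rule: first column holds
   identifiers; the remaining columns pair up as (value, p-value) series when
   their count is even, and are value-only series when odd.
   `match_identifiers()` matches identifiers to node labels exactly and
   case-sensitively — no fuzzy mapping, no cross-database translation.
3. **Styling** — per node and sample, a fill color:
   * *gradient mode*: a symmetric piecewise-linear RGB ramp
     `down_color → neutral → up_color` over `[-v_max, +v_max]`
     (defaults red `#FF0000` / white / green `#00FF00`), clamped beyond
     `±v_max`, which by default is the largest |value| over **all** samples
     so every panel shares one scale;
   * *significance mode*: color by the sign of the value only when
     `p ≤ cutoff` (presets 0.001, 0.01, 0.05, 0.1), else neutral.
   Nodes without data are shown, greyed (`#C0C0C0`), or hidden — hiding a
   node also hides its incident edges. Decorations are always greyed.
4. **Rendering** — `build_panels()` replicates the styled map per sample,
   `render_svg()` lays the panels out row-major in a near-square grid and
   emits a deterministic standalone SVG; `autoplot()` gives a quick ggplot2
   preview of the same panels.

A seeded fixture generator (`make_pathway()`, `make_measurements()`) produces
GPML + CSV test inputs shaped like a five-timepoint expression time course,
so the whole pipeline is testable without downloads.

## Worked example

```r
library(pathpanels)

fx  <- make_pathway(n_nodes = 30, n_edges = 35, n_decorations = 3, seed = 7)
tbl <- read_delimited_table(make_measurements(fx$map, seed = 7)$csv)

binding <- match_identifiers(fx$map, tbl)
glance(binding)
#> # A tibble: 1 × 4
#>   n_series n_matched_nodes n_unmatched_identifiers n_values
#>      <int>           <int>                   <int>    <int>
#> 1        5              27                       3      135
```

27 of the table's 30 distinct identifiers matched a map node; the 3
unmatched ones (novel identifiers the generator injected) are reported but
do not stop the run. Each of the 5 samples contributes up to 27 bound
values, giving 135 node–sample data points.

```r
style  <- visual_style(mode = "p_value_cutoff", cutoff = 0.1,
                       no_data_policy = "grey")
panels <- build_panels(fx$map, binding, style)
doc    <- render_svg(panels)
doc
#> <rendered_document: SVG 2320 x 788, 50393 bytes>
write_svg(doc, "multiples.svg")
```

The SVG holds five panel groups — one per time point (`0h, 2h, 12h, 24h,
72h`) — each a copy of the same 33-node map in which green nodes gained
transcript abundance significantly (p ≤ 0.1), red nodes lost it, white nodes
changed without significance, and grey nodes are decorations or carry no
data.

The same run from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pathpanels.R", package = "pathpanels"))')
Rscript "$CLI" fixtures --seed 7 --out-prefix demo
Rscript "$CLI" --network demo.gpml --data demo.csv \
  --mode pvalue --cutoff 0.1 --no-data grey --out multiples.svg
```

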