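# enroute

Path extraction and linearized multi-omics visualization for pathway maps.

Curated pathway maps (KEGG, WikiPathways) keep molecular interactions in a
fixed, recognizable layout, but their nodes are far too small to show the
hundreds of samples of a modern experiment — let alone several data types
at once. `enroute` implements the strategy of extracting a **path of
interest** from the map and unrolling it into a **linear, top-down view**
with one uniform-height data row per mapped gene, while the original map
stays available as an annotated overview. It is aimed at computational
biologists who want to relate grouped mRNA expression, copy-number and
mutation data to the successive stages of a signaling cascade or
metabolic route.

The package provides, as a library plus a command-line tool:

* **Pathway model** — KGML and GPML parsers into one attributed directed
  graph preserving node geometry (`parse_kgml()`, `parse_gpml()`), and a
  round-tripping KGML writer for fixtures (`write_kgml()`).
* **Path selection** — iterative extension (`extend_path()`), exhaustive
  enumeration of all simple alternatives between a start and an end node
  with deterministic shortest-first ordering (`find_alternatives()`), a
  *force mode* that bridges edges missing from the database
  (`force_edge()`), and extension previews (`preview_extensions()`).
* **Linearization** — joining/leaving branch abstraction per path node
  (`compute_branches()`), branch switching with the walk-until-ambiguous
  rule (`switch_branch()`), branch expansion (`expand_branch()`).
* **Data mapping** — typed gene×sample matrices (numerical, five-level
  ordinal copy number, binary mutation) with named, possibly overlapping
  sample groups; multi-mapping resolution of nodes (including complex
  nodes) onto rows (`resolve_mappings()`); pooled and per-group summary
  statistics (`node_summary()`, `group_summary()`), quantitative
  copy-number categorization (`categorize_cnv()`), branch data previews.
* **Rendering** — deterministic SVG of the annotated overview (diverging
  on-node colors, variance bars, missing-data markers, corridor highlight
  with node cut-outs and obstacle-avoiding edge routing) and of the
  linearized view with six cell encodings (per-sample bars, mean±SD bar,
  copy-number bars/histogram, mutation matrix/histogram), ribbons,
  alternating shades and sample highlighting.
* **Fixtures** — seeded generators of synthetic pathways and coupled
  omics matrices (`make_pathway()`, `make_omics()`,
  `write_fixture_set()`), so everything runs offline.

Given a node's resolved rows *R*, selected samples *S* and non-missing
values *x(r,s)*, the on-node statistics are the pooled mean and
population standard deviation

    mean = (1/n) Σ x(r,s),    sd = sqrt((1/n) Σ (x(r,s) − mean)²)

over all *n* non-missing pairs in *R × S*; for binary data the mean is
the mutated fraction, and ordinal copy-number codes (−2 … 2) enter the
mean directly and are additionally counted per category.

## Worked example

```r
library(enroute)

cfg <- fixture_config(seed = 1)       # the synthetic study conditions
g   <- make_pathway(cfg)
g
#> pathway_graph 'synthetic001' (kgml): 15 nodes, 21 edges, image 500x300 px
#>   kinds: gene=14, group=1

alts <- find_alternatives(g, "n01", "n04")
alts
#> path_alternatives n01 -> n04: 4 path(s) [ok]
#>   *[1] n01 -> n02 -> n04
#>    [2] n01 -> n03 -> n04
#>    [3] n01 -> n03 -> n08 -> n06 -> n04
#>    [4] n01 -> n03 -> n08 -> n06 -> n13 -> n02 -> n04
```

Four simple paths connect the chosen start and end node; the first is a
shortest path and is selected by default. Mapping the synthetic
expression matrix onto one of its nodes pools all rows the node's member
genes resolve to:

```r
om <- make_omics(g, cfg)
node_summary("n02", om$datasets$mrna, graph = g)
#> node_summary: mean 0.5416, sd 1.045 over 68 value(s) (3 row(s) x 24 sample(s)), missing present
```

`n02` multi-maps to 3 gene rows; 68 of the 72 cells are observed (the
generator injects missing values), their pooled mean is 0.54 on the
log-expression scale and the missing-data marker will be set. Linearizing
the selected path abstracts all off-path neighbors into countable branch
groups and gives every mapped gene its own row:

```r
p    <- current_path(alts)
spec <- compute_branches(g, p)
spec
#> linear_path_spec: 3 node(s), 5 branch group(s)
#>   joining @n01: 1 head(s)
#>   leaving @n01: 1 head(s)
#>   joining @n02: 2 head(s)
#>   joining @n04: 3 head(s)
#>   leaving @n04: 1 head(s)

lay <- layout_linear(g, spec, om$datasets, om$groupings)
lay
#> linear_layout: 3 node block(s), 6 column(s), 620x190 px
#>   n01: 1 row(s), y [26, 56] (light)
#>   n02: 3 row(s), y [68, 122] (dark)
#>   n04: 1 row(s), y [134, 164] (light)

svg_overview <- render_overview(g, om$datasets$mrna, om$groupings$mrna,
                                selection = alts)
svg_linear   <- render_enroute(g, lay, om$datasets, om$groupings)
```

Both strings are complete SVG documents; identical inputs always produce
byte-identical output.

The same pipeline runs from the shell:

```sh
inst/cli/enroute simulate --seed 1 --out demo/
inst/cli/enroute paths --pathway demo/pathway.kgml --start n01 --end n04
inst/cli/enroute run --config run.yaml
```

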