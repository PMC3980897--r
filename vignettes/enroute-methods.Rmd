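---
title: "Methods: path extraction and linearized omics views on pathway maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path extraction and linearized omics views on pathway maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enroute)
```

## The problem

Curated pathway maps (KEGG, WikiPathways) place genes, compounds and
complexes in a hand-drawn layout that practitioners recognize, and they
ship as XML (KGML, GPML) carrying both topology and node geometry. Mapping
experiment data onto such a map by coloring nodes works for a single
aggregate value, but not for hundreds of samples across several data
types: the nodes are simply too small. The strategy implemented here keeps
the map for orientation and *extracts a path of interest*, which is then
unrolled into a linear, top-down view with room for one uniform-height
data row per mapped gene. Four requirements drive the design: scale in the
number of samples, heterogeneity of data types (numerical expression,
ordinal copy number, binary mutation status), multi-mapping of several
genes onto one node, and preservation of the original map layout.

## Pathway model

`parse_kgml()` and `parse_gpml()` produce the same attributed directed
graph: nodes with a center-anchored bounding box in image pixels (origin
top-left, y down — the KGML convention; GPML coordinates are adopted
unchanged), a kind (`gene`, `compound`, `map_link`, `group`), an ordered
list of namespace-qualified member identifiers, and children for group
("complex") nodes. Relations and reaction substrate/product pairs become
typed edges; undirected interactions (GPML lines without arrowheads) are
stored once and traversable both ways, so a drawing style cannot block a
path search. Edges that reference a group attach to the group node itself
and are *not* expanded to its children — decomposition into genes happens
at data-mapping time, not in the topology. Edge semantics beyond direction
(activation vs. inhibition) are deliberately unused by the path logic: a
signaling cascade of interest routinely crosses inhibiting edges.

Member identifiers are stored as `namespace:id` strings (`entrez:1956`).
There is no online identifier translation; an optional two-column alias
table maps dataset row ids onto member ids offline, because measurement
platforms and pathway databases frequently use different aliases for the
same gene.

`write_kgml()` emits a KGML dialect chosen so that parsing its output
reproduces the graph exactly (ids, members, boxes, edges); it is what the
fixture generator writes and what the round-trip tests exercise.

## Path selection

Two modes can be combined freely:

* **Iterative** (`extend_path()`): grow a path one adjacent node at a
  time at either end, respecting edge direction.
* **Start–stop** (`find_alternatives()`): enumerate *all* simple paths
  between two nodes. The enumeration is a bounded depth-first search over
  sorted adjacency lists (defaults `max_len = 20` edges,
  `max_paths = 64`), sorted by length and then lexicographically by node
  sequence, so the first entry is a shortest path and output is
  independent of the order in which edges appeared in the file. When
  truncation is in effect a breadth-first shortest path is injected
  before sorting so the default selection is still shortest. We chose
  plain bounded enumeration over a shortest-path-only algorithm because
  the interaction contract is to *show every alternative*, not just an
  optimal one; truncation is flagged on the result.

Paths are simple: a repeated node is rejected. True cycles could in
principle be meaningful selections, but every rendered figure of the
technique shows simple paths, and excluding revisits keeps the
enumeration finite; this is a documented limitation. `force_edge()`
implements the force mode for incomplete or outdated maps: the path is
extended across a non-edge and the injected pair is recorded so renderers
can draw it dashed. Forcing a pair that does exist behaves exactly like a
normal extension and records nothing. `preview_extensions()` lists the
immediate (one-step) continuations at both ends; we read the preview
interaction as immediate neighbors, not transitive closures, which is the
conservative reading of the original interface.

## Linearization and branches

`compute_branches()` turns a selected path into the linear specification:
for every path node, off-path in-neighbors form one *joining* group and
off-path out-neighbors one *leaving* group (the path's own
predecessor/successor never counts). Heads are ordered by label then id
for reproducible output. `switch_branch()` re-routes the path onto a
branch: the kept segment is the prefix (leaving) or suffix (joining) at
the anchor, and the walk from the chosen head appends nodes as long as
the current node has *exactly one* eligible continuation — a
successor/predecessor not already on the path. Zero continuations is a
dead end; two or more means a new branch opens and the walk stops there.
This interpretation guarantees termination (each step consumes a node)
and reproduces the reference scenario in which a walk down a receptor
branch ends precisely at the first node with two leaving branches.
Forced edges outside the kept segment are discarded, since the walk
replaces the segment they belonged to. At most one branch group is
expanded at a time; expanding one collapses the others, which the
renderer grays out.

## Data mapping

Datasets are gene-by-sample matrices of one declared type: `numerical`,
`ordinal_cnv` (five-level scale, homozygous deletion … high gain, stored
as integer codes −2…2) or `binary`. Groups of samples are named, ordered,
may overlap, and each group draws from exactly one dataset.

`resolve_mappings()` is the multi-mapping step: gene nodes map to every
dataset row matching a member (in member order, after alias translation);
group nodes concatenate their children child-major and deduplicate;
compounds and map links map to nothing. `node_summary()` pools the
resolved values (missing excluded — we exclude rather than impute, and
any missing cell or an empty resolution raises the missing-data marker)
and reports mean and **population** standard deviation. Population rather
than sample SD is a deliberate choice: it is defined for single-sample
groups and the variance bar is a relative visual cue, not an inferential
statistic. Ordinal copy-number values enter the mean through their
integer codes (the scale is symmetric around "normal" = 0, so the
diverging color map is meaningful), and additionally yield per-category
counts; for binary data the mean *is* the mutated fraction.
`categorize_cnv()` maps quantitative, log-ratio-like copy-number values
onto the five categories with symmetric thresholds `t_low = 0.3`,
`t_high = 1.0` (boundaries closed away from zero); the defaults
correspond to common log2-ratio cutoffs and are configuration-exposed
because platforms differ.

An on-node average always refers to one explicitly chosen dataset; we do
not pool across data types, since the overview shows one type at a time.

## Rendering

Both views are serialized by a small deterministic SVG writer: fixed
attribute order, fixed number formatting, no timestamps — identical
inputs give byte-identical documents, which the tests assert.

**Overview.** Nodes are drawn at their original boxes and filled through
a blue-white-red diverging map (white anchored at the neutral value:
0 for expression scales and copy-number codes); binary data uses a
gray-to-red ramp over the mutated fraction. A green bottom bar encodes
the standard deviation relative to the largest SD on the map ("almost
full" = highest variation present); a small lower-left rectangle marks
missing data. The selected path — or all enumerated alternatives, each
in its own color with the selected one emphasized — is wrapped in a
corridor.

**Corridor geometry.** The original implementation used a potential-field
set-outline algorithm rendered by marching squares. We replace it with an
exact geometric construction with the same contracts: the corridor is the
union of the member boxes inflated by `radius` and of rectangular strokes
of half-width `radius` along the routed edges; the exact member boxes are
reported as holes and the whole region is filled with the even-odd rule,
so node interiors stay unobscured on top of a color-coded map. Edge
routing (`route_edge()`) returns the straight center-to-center segment
when it clears every off-path box inflated by `margin` (touching at
exactly the margin counts as blocked), and otherwise the shortest
orthogonal detour found by Dijkstra on the lattice spanned by the
endpoint and obstacle coordinates. Corridor strokes use orthogonal
routing throughout with clearance `radius + margin`, which makes the
union rectilinear — computed exactly by coordinate compression and
boundary tracing, with ring vertices taken verbatim from the input
coordinates — and guarantees the stroke sides keep at least `margin`
distance from every off-path box. Corners are square; a corner radius is
a purely cosmetic option we left out of the geometry.

**Linear view.** The layout stacks node blocks top-down in path order;
block height is `max(min_node_height, rows × row_height)` with a uniform
`row_height` (default 18 px), so a 16-gene complex node occupies exactly
16 rows. Ribbons connect each node glyph to its row block and background
shades alternate per node (two grays, configuration-exposed) to keep the
row-to-node association readable. Detailed columns get width proportional
to group size (`bar_width` per sample); abstract columns share one fixed
width and baseline so abstract values are comparable down the path. The
six cell encodings follow the reference design: per-sample bars with a
left-to-right gradient (the gradient exists to separate adjacent bars
without outline strokes); mean bar with SD whiskers; copy-number bars
redundantly encoded by length, color and orientation (ordinal codes use
fixed long:short = 2:1 lengths; quantitative values would scale with
magnitude capped at `t_high`); a five-bin category histogram; a
mutation matrix with a fixed row count (default 3) filled column-major —
the fill order is unspecified in the reference, column-major preserves
sample order left-to-right; and a two-bin mutation histogram. Sample
highlights outline the sample's marks in every group where it occurs.

## Synthetic data generator

`make_pathway()`/`make_omics()` define the study conditions for all
tests: a connected map on a jittered grid (46×17 px boxes, 110×60 px
spacing — jitter bounds keep boxes disjoint and leave the corridor
defaults collision-free by construction), a planted diamond guaranteeing
at least two alternatives between `n01` and `n04`, one complex node with
16 member genes, and one group node. Omics defaults: two groups (tumor,
normal) of 12 samples; copy-number category probabilities skewed toward
gains in the tumor group (0.05/0.10/0.50/0.20/0.15 from homozygous
deletion to high gain, versus 0.02/0.08/0.80/0.08/0.02 in normal);
expression `shift[group] + rho × code + N(0, 1)` with `shift = 1` in
tumor, `rho = 0.5`; mutation rates 0.2/0.05; 2% missing cells. These
magnitudes are typical of log-scale expression panels with a real
amplification–expression coupling and give planted effects that the
summaries recover. The generator emulates grouped, coupled, partially
missing matrices — it does not emulate real pathway topology statistics,
label aliasing chaos, batch effects or dependence between genes, so
passing tests demonstrate correctness of the machinery, not robustness to
every real-world artifact.

Problem sizes used by the checks, chosen to make the oracles exhaustive
and the statistics tight: enumeration is verified against brute force on
200 random graphs of up to 12 nodes; statistical recovery uses 1000
samples per group (binomial SEs below 1.3 percentage points); geometry is
swept over 200 generated maps; round-trips over 100.

## Numerical and degenerate-input choices

* Zero non-missing values: summaries return `defined = FALSE` with `NA`
  statistics instead of propagating `NaN`.
* Tie-breaks are lexicographic everywhere (path ordering, branch heads,
  neighbor lists) — never dependent on insertion order.
* `selected` indices are 1-based, following R convention.
* Degraded routing: if no clear detour exists inside the lattice, the
  straight segment is returned with a warning rather than failing the
  render.
* Seeds fully determine fixture output; the matrices are written with
  full-precision decimal formatting so files round-trip losslessly.

## Command line

The `inst/cli/enroute` Rscript exposes `simulate`, `paths`, `extract`,
`render-overview`, `render-path` and `run` over a YAML configuration
(exit codes: 0 ok, 2 usage, 3 data error, 4 no path), so the pipeline can
be driven without writing R.

## Known limitations

Paths cannot span multiple pathways; non-simple (cyclic) selections are
rejected; anchors in GPML resolve to the host interaction's target node,
which flattens edge-attached catalysis onto the node graph; interactive
features of the original tool (brushing, tooltips, scrolling, animated
expansion) are out of scope — expansion state is an input, not a gesture.
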