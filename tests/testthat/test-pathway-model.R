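test_that("minimal KGML with two gene entries and one relation parses", {
  xml <- '<?xml version="1.0"?>
  <pathway name="path:test" title="mini">
    <entry id="1" name="hsa:1956" type="gene">
      <graphics name="EGFR" x="100" y="50" width="46" height="17"/>
    </entry>
    <entry id="2" name="hsa:2064" type="gene">
      <graphics name="ERBB2" x="200" y="50" width="46" height="17"/>
    </entry>
    <relation entry1="1" entry2="2" type="ECrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
  </pathway>'
  g <- parse_kgml(xml)
  expect_length(g$nodes, 2)
  expect_equal(nrow(g$edges), 1)
  expect_true(g$edges$directed)
  expect_equal(g$edges$relation, "activation")
  expect_equal(g$nodes[["1"]]$label, "EGFR")
})

test_that("multi-identifier entry names become the members list", {
  xml <- '<pathway name="p"><entry id="1" name="hsa:1956 hsa:2064" type="gene">
    <graphics name="EGFR" x="10" y="10" width="40" height="20"/></entry></pathway>'
  g <- parse_kgml(xml)
  expect_equal(g$nodes[["1"]]$members, c("entrez:1956", "entrez:2064"))
})

test_that("KGML group entries keep their component children as nodes", {
  g0 <- mk_graph(c("a", "b", "c"))
  grp <- pathway_node("grp", "group", "cplx", c(400, 300, 60, 40),
                      children = c("a", "b", "c"))
  g0 <- pathway_graph("p", "p", c(g0$nodes, list(grp)), g0$edges)
  g <- parse_kgml(write_kgml(g0))
  expect_equal(g$nodes[["grp"]]$kind, "group")
  expect_equal(g$nodes[["grp"]]$children, c("a", "b", "c"))
  expect_true(all(c("a", "b", "c") %in% names(g$nodes)))
})

test_that("KGML parse errors and degraded inputs are reported", {
  expect_error(parse_kgml("<pathway><entry></pathway>"), "parse error")
  expect_error(parse_kgml("<notapathway/>"), "root element")
  xml <- '<pathway name="p">
    <entry id="1" name="hsa:1" type="gene"/>
    <entry id="2" name="hsa:2" type="gene">
      <graphics name="g2" x="1" y="1" width="2" height="2"/></entry>
    <relation entry1="2" entry2="9" type="PPrel"/>
  </pathway>'
  expect_warning(expect_warning(g <- parse_kgml(xml), "no graphics"),
                 "missing entry")
  expect_length(g$nodes, 1)
  expect_equal(nrow(g$edges), 0)
})

test_that("KGML write/parse round-trips structure and geometry exactly", {
  for (seed in 1:8) {
    g <- make_pathway(fixture_config(seed = seed))
    g2 <- parse_kgml(write_kgml(g))
    expect_identical(names(g2$nodes), names(g$nodes))
    expect_identical(lapply(g2$nodes, `[[`, "members"),
                     lapply(g$nodes, `[[`, "members"))
    expect_identical(lapply(g2$nodes, `[[`, "kind"),
                     lapply(g$nodes, `[[`, "kind"))
    expect_equal(lapply(g2$nodes, `[[`, "bbox"), lapply(g$nodes, `[[`, "bbox"))
    key <- function(e) sort(paste(e$source, e$target, e$relation, e$directed))
    expect_identical(key(g2$edges), key(g$edges))
    expect_equal(g2$image_size, g$image_size)
  }
})

test_that("empty graph round-trips through the KGML dialect", {
  g <- pathway_graph("empty", "empty")
  g2 <- parse_kgml(write_kgml(g))
  expect_length(g2$nodes, 0)
  expect_equal(nrow(g2$edges), 0)
})

test_that("parsing never invents edges beyond the source relation count", {
  g <- make_pathway(fixture_config(seed = 11))
  doc <- write_kgml(g)
  n_rel <- length(gregexpr("<relation ", doc, fixed = TRUE)[[1]])
  expect_lte(nrow(parse_kgml(doc)$edges), n_rel)
})

test_that("GPML documents parse into nodes, groups and directed edges", {
  gpml <- '<?xml version="1.0"?>
  <Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="demo">
    <Graphics BoardWidth="600" BoardHeight="400"/>
    <DataNode TextLabel="EGFR" GraphId="d1" Type="GeneProduct" GroupRef="gr1">
      <Graphics CenterX="100" CenterY="80" Width="80" Height="20"/>
      <Xref Database="Entrez Gene" ID="1956"/>
    </DataNode>
    <DataNode TextLabel="SHC2" GraphId="d2" Type="GeneProduct" GroupRef="gr1">
      <Graphics CenterX="100" CenterY="120" Width="80" Height="20"/>
      <Xref Database="Entrez Gene" ID="25759"/>
    </DataNode>
    <DataNode TextLabel="GRB2" GraphId="d3" Type="Protein">
      <Graphics CenterX="300" CenterY="100" Width="80" Height="20"/>
      <Xref Database="" ID=""/>
    </DataNode>
    <DataNode TextLabel="ATP" GraphId="d4" Type="Metabolite">
      <Graphics CenterX="300" CenterY="200" Width="60" Height="20"/>
      <Xref Database="HMDB" ID="HMDB00538"/>
    </DataNode>
    <Interaction>
      <Graphics>
        <Point X="140" Y="120" GraphRef="d2"/>
        <Point X="260" Y="100" GraphRef="d3" ArrowHead="Arrow"/>
      </Graphics>
    </Interaction>
    <Group GroupId="gr1" GraphId="g1"/>
  </Pathway>'
  g <- parse_gpml(gpml)
  expect_setequal(names(g$nodes), c("d1", "d2", "d3", "d4", "g1"))
  expect_equal(g$nodes[["d1"]]$members, "entrez:1956")
  # no usable Xref: falls back to the label
  expect_equal(g$nodes[["d3"]]$members, "symbol:GRB2")
  expect_equal(g$nodes[["d4"]]$kind, "compound")
  expect_equal(g$nodes[["g1"]]$kind, "group")
  expect_setequal(g$nodes[["g1"]]$children, c("d1", "d2"))
  expect_equal(nrow(g$edges), 1)
  expect_true(g$edges$directed)
  expect_equal(g$edges$source, "d2")
  expect_equal(g$image_size, c(600, 400))
})

test_that("GPML interactions without arrowheads are undirected and anchors resolve", {
  gpml <- '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="anch">
    <DataNode TextLabel="A" GraphId="a" Type="GeneProduct">
      <Graphics CenterX="10" CenterY="10" Width="10" Height="10"/></DataNode>
    <DataNode TextLabel="B" GraphId="b" Type="GeneProduct">
      <Graphics CenterX="90" CenterY="10" Width="10" Height="10"/></DataNode>
    <DataNode TextLabel="C" GraphId="c" Type="GeneProduct">
      <Graphics CenterX="50" CenterY="90" Width="10" Height="10"/></DataNode>
    <Interaction><Graphics>
      <Point X="10" Y="10" GraphRef="a"/>
      <Anchor Position="0.5" GraphId="an1"/>
      <Point X="90" Y="10" GraphRef="b"/>
    </Graphics></Interaction>
    <Interaction><Graphics>
      <Point X="50" Y="90" GraphRef="c"/>
      <Point X="50" Y="10" GraphRef="an1" ArrowHead="TBar"/>
    </Graphics></Interaction>
    <Interaction><Graphics>
      <Point X="1" Y="1" GraphRef="nope"/>
      <Point X="2" Y="2" GraphRef="c"/>
    </Graphics></Interaction>
  </Pathway>'
  expect_warning(g <- parse_gpml(gpml), "unresolvable")
  expect_equal(nrow(g$edges), 2)
  undirected <- g$edges[g$edges$source == "a", ]
  expect_false(undirected$directed)
  anchored <- g$edges[g$edges$source == "c", ]
  expect_equal(anchored$target, "b")
  expect_equal(anchored$relation, "inhibition")
})

test_that("neighbors respects direction, undirected edges and ordering", {
  g <- mk_graph(c("A", "B", "C", "D", "X"),
                c("A>C", "A>B", "B>D", "C>D", "A-X"))
  expect_equal(neighbors(g, "A", "out")$node, c("B", "C", "X"))
  expect_equal(neighbors(g, "A", "in")$node, "X")
  expect_equal(neighbors(g, "D", "in")$node, c("B", "C"))
  expect_equal(neighbors(g, "X", "out")$node, "A")
  iso <- mk_graph("Z")
  expect_equal(nrow(neighbors(iso, "Z", "both")), 0)
  expect_error(neighbors(g, "nope"), "unknown node")
})

test_that("graph invariants are enforced at construction", {
  expect_error(pathway_node("x", "gene", bbox = c(0, 0, 0, 10),
                            members = "entrez:1"), "positive width")
  expect_error(pathway_node("x", "compound", members = "entrez:1"), "empty")
  expect_error(mk_graph(c("A", "A")), "duplicate")
  expect_error(pathway_graph("p", "p",
                             list(pathway_node("a", "gene", members = "m:1")),
                             data.frame(source = "a", target = "zz",
                                        relation = "other", directed = TRUE)),
               "endpoints")
})
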