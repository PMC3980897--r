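Package: enroute
Title: Path Extraction and Linearized Multi-Omics Visualization for Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses KEGG (KGML) and WikiPathways (GPML) pathway descriptions
    into an attributed directed graph that preserves the original map
    geometry, extracts simple paths between user-chosen nodes (with
    enumeration of all alternatives and a force mode for edges missing from
    the database), linearizes a selected path into a top-down layout with
    abstracted joining and leaving branches, maps grouped gene-by-sample
    omics matrices (mRNA expression, ordinal copy-number calls, binary
    mutation status) onto path nodes with multi-mapping resolution, and
    renders both an annotated pathway overview and the linearized path view
    as deterministic SVG. Includes seeded generators for synthetic pathways
    and omics matrices so all functionality can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
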