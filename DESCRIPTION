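Package: anatomygraphs
Title: Instance-Based Anatomy Knowledge Graphs in Typed Named Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Record morphological descriptions of individual specimens as
    instance-based RDF knowledge graphs, fragmented into typed named graphs
    (one descriptive statement per graph) held in a quad store. Builders
    cover document structure, partonomies linked by BFO 'has part', PATO
    quality and measurement annotation with Units Ontology units, and
    OBI-style assay, specimen-collection and specimen-history provenance.
    Query templates locate a document's graphs and compute parthood,
    description and metadata unions; data views resolve named selections of
    named-graph classes; per-class shape validation and whole-document
    referential-integrity checks enforce the data standard; stores round-trip
    through TriG and N-Quads, and results export to CSV and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
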