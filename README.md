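# anatomygraphs

Morphological descriptions of individual specimens, recorded as
instance-based RDF knowledge graphs and managed as **typed named graphs in a
quad store**.

Morphologists describing specimens need their data to be findable,
comparable and reusable (FAIR), which free-text descriptions are not. The
instance-based alternative types every described part, quality and
measurement as an ontology individual with its own IRI — UBERON/HAO anatomy
classes, PATO qualities, UO units, OBI processes, IAO document structure —
and because such a graph is pure ABox with no blank nodes, it can be
fragmented into minimal sub-graphs and reassembled by set union *without
losing information*. This package implements that data model for R users:

* **one descriptive statement per named graph** — a parthood edge
  (`bfo:has part`), a quality, or a measurement, each in a graph typed by a
  named-graph class with its own validation scheme;
* a **document layer** (IAO sections) and an **assertions graph** wiring the
  description graphs to the results section and the metadata graphs (OBI
  assays, specimen collection, specimen history DAGs) to the methods
  section;
* **query templates** — locate the document/assertions graphs and the
  instance anatomy, then compute parthood, description and metadata unions
  (the description union *is* the Anatomy Knowledge Graph);
* **data views** — named sets of named-graph classes, optionally
  unit-filtered (e.g. metre-based lengths only), resolved per document;
* per-class **shape validation** plus whole-document referential integrity;
* **TriG / N-Quads** round-tripping, CSV and JSON export, a seeded synthetic
  description generator, and a CLI (`generate | build | validate | query |
  export`).

## Worked example

`worked_example()` materializes the canonical small description: a
hymenopteran whole organism with a head (volume 0.25 ml) and a thorax
(rough surface texture), one microscopy assay, a live-trap collection and a
specimen history that forks into a voucher and a tissue sample — each
named-graph class represented exactly once (the partonomy needs three
parthood graphs: the root shape plus two child shapes).

```r
library(anatomygraphs)
fx <- worked_example()
fx$store
#> <quad_store> 10 named graphs, 92 quads

validate_document(fx$store, fx$doc)
#> <validation_report> PASSED: 0 error(s), 0 warning(s)

pu <- parthood_union(fx$store, fx$anatomy, fx$assertions_graph)
extract_partonomy(pu)
#> <partonomy> 3 parts, 2 edges
#>   root: https://example.org/akg/organism/5c5581ec-1 (whole organism of specimen A)

head(export_csv(resolve_view(fx$store, fx$doc, "general-measurements")), 3)
#>                                               s                                               p                                         o                             o_datatype
#> 1       https://example.org/akg/head/5c5581ec-1       http://purl.obolibrary.org/obo/RO_0000086 https://example.org/akg/volume/5c5581ec-1
#> 2 https://example.org/akg/milliliter/5c5581ec-1 http://www.w3.org/1999/02/22-rdf-syntax-ns#type http://purl.obolibrary.org/obo/UO_0000098
#> 3     https://example.org/akg/volume/5c5581ec-1      http://purl.obolibrary.org/obo/IAO_0000004                                      0.25 http://www.w3.org/2001/XMLSchema#float
```

The 10 named graphs are the document graph, three parthood graphs (the
2-statement root shape and two 3-statement child shapes), one texture graph
(2 statements), one volume graph (5 statements), the assay, collection and
history graphs, and the assertions graph; the description union has
8 + 2 + 5 = 15 statements. The `general-measurements` view returns the
volume graph's five statements, while `lengths-and-distances` is empty
here — a milliliter is not a metre-based unit.

From a shell, the same store can be produced and queried through the
installed CLI script (symlink it onto your `PATH` if you use it often):

```sh
akg=$(Rscript -e 'cat(system.file("exec", "anatomygraphs", package = "anatomygraphs"))')
Rscript "$akg" generate --seed 1 --out desc.trig
Rscript "$akg" validate --in desc.trig           # exit 0, report on stderr
Rscript "$akg" query --in desc.trig --view parthood-view --out partonomy.csv
Rscript "$akg" export --in desc.trig --to json --out desc.json
```

See `vignettes/anatomy-knowledge-graphs.Rmd` for the model, the validation
schemes, the generator's assumptions and the design decisions.

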