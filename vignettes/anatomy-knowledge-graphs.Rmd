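---
title: "Instance anatomy knowledge graphs in typed named graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance anatomy knowledge graphs in typed named graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatomygraphs)
```

## The model

A morphological description of an individual specimen can be recorded as an
*instance-based* RDF graph: every anatomical part, every quality and every
measurement is an ontology individual with its own IRI, typed by a class from
a community ontology (UBERON or HAO for anatomy, PATO for qualities, UO for
units, OBI for processes, IAO for document structure). Because the graph is
pure ABox — there are no blank nodes anywhere in the model — it can be
fragmented into arbitrarily small sub-graphs and reassembled by plain set
union without losing information. That losslessness is the property this
package is built around, and the one its checks exercise hardest.

The unit of fragmentation is the **named graph**: a set of triples identified
by its own IRI. Adding the graph IRI to each triple turns triples into quads,
which is what the `quad_store()` container holds. Each named graph
instantiates exactly one **named-graph class**, and each class carries
exactly one **data scheme** describing the statement shape its instances must
have. Graphs of the same class are therefore structurally comparable across
descriptions — the basis for cross-description alignment and for data views.

The built-in classes and their schemes:

| class key                     | content                                            | scheme shape |
|------------------------------|----------------------------------------------------|--------------|
| `document`                   | an `iao:document` and its eight sections           | 1 document type, sections typed and attached, assertions graph registered |
| `assertions`                 | the wiring of the whole document                   | 1 instance anatomy, every referenced graph typed |
| `parthood`                   | one part: type, label, and (except for the root) one `bfo:has part` edge from its parent | exactly 1 type, 1 label, at most 1 edge |
| `anatomical-surface-texture` | one quality: bearer → freshly minted PATO texture instance | exactly 1 `has_quality`, quality typed in the matching family |
| `anatomical-structure-volume`, `anatomical-structure-length` | one measurement: quality instance, finite float value, typed UO unit | the 5-statement measurement shape |
| `assay-data`                 | one observation: specimen input, description graphs as outputs, who/where/when/how | ≥1 input, ≥1 output, provenance instances typed and attached |
| `specimen-collection`        | one collection process: one material input, one specimen output | exactly 1 input and 1 output, both typed |
| `specimen-history`           | the DAG of specimens derived by material processing, forks allowed | inputs/outputs typed, balanced, acyclic, connected |

One *descriptive* statement per graph is deliberate: a parthood graph holds
exactly one parthood edge, a quality graph one quality, a measurement graph
one measurement. Fine granularity is what lets metadata be attached
differentially — an assay names exactly the graphs that resulted from it —
and what makes views cheap to resolve.

## Queries and views

The query templates are first-class operations with pattern semantics
equivalent to the SPARQL they would compile to; the operation contract, not
SPARQL syntax, is normative, which keeps them testable without standing up an
endpoint:

1. `locate_document_graph()` — the unique graph containing
   `(doc, rdf:type, iao:document)`;
2. `locate_assertions_graph()` — the IRI typed as assertions graph inside the
   document graph;
3. `locate_instance_anatomy()` — the individual typed `instance anatomy`
   inside the assertions graph;
4. `parthood_union()` / `description_union()` / `metadata_union()` — set
   unions over the graphs attached by `has part` to the anatomy (optionally
   class-filtered) or to the methods section.

Every one of them is checked against a brute-force scan over the flat quad
table. Result ordering is lexicographic by IRI wherever the underlying answer
is an unordered set, so all outputs are deterministic.

A **data view** is a named set of named-graph classes plus an optional unit
filter, resolved per document as the union of the matching graphs.
`parthood-view`, `general-measurements` and `lengths-and-distances` ship
registered; the last one keeps only graphs whose unit instance is typed by a
metre-based unit (metre, centimetre, millimetre, micrometre by default —
extendable by registering more units with family `"metre-unit"`). Views obey
a simple algebra (additivity over disjoint class sets, monotonicity in the
class set, filtered ⊆ unfiltered) that the test suite asserts on generated
stores.

## Parameters that matter

* **Predicate table** (`default_predicates()`). The parthood predicate is
  fixed to BFO 0000051 — that one is named by the model. Everything else is
  configuration: quality/measurement predicates default to RO 0000086,
  IAO 0000004 and IAO 0000039; assay input/output to OBI 0000293/0000299;
  agent and place to PROV; date to Dublin Core terms; the few predicates
  with no established IRI (free text, device, protocol, the
  assertions-graph registration) live in the package's own `prop/`
  namespace. Builders take the table as an argument, so a deployment can
  swap any entry without touching builder code.
* **Named-graph class IRIs.** The model names its classes ("parthood named
  graph", "instance anatomy", …) without publishing IRIs, so the package
  mints stable ones under `https://w3id.org/anatomygraphs/ngo/` and records
  them in the bundled term catalog, keeping them citable and constant across
  runs.
* **IRI minting** (`iri_minter()`). IRIs are `base + kind + tag + counter`,
  with the tag a hex fingerprint of the seed. Determinism (same seed, same
  call sequence ⇒ same IRIs) makes fixtures byte-reproducible; the per-kind
  counter makes collisions impossible within a run. Nothing about an IRI is
  semantically load-bearing.
* **Term catalog** (`inst/extdata/term_catalog.tsv`). A small offline
  snapshot of every class the builders use, keyed for lookup, with a
  `family` column that drives two checks: quality classes must belong to the
  family of their named-graph class (a texture graph cannot hold a volume
  quality), and unit filters select on unit families. The catalog is data:
  `register_term()`, `register_ng_class()` and `register_namespace()` extend
  it at run time, and registering a named-graph class requires supplying (or
  sharing) a validation scheme, preserving the class–scheme bijection.
  One catalog note: the source model attributes the "microscopy assay" class
  to IAO although assays are OBI territory; the catalog records the label
  with its source marked "IAO (as cited)" and a project-namespace IRI rather
  than guessing an ontology ID that may not exist.

## Validation

`validate_named_graph()` interprets the class's declarative rule list
(counts per predicate, typed-object and typed-attached constraints, float
finiteness, DAG checks). `validate_document()` adds cross-graph integrity:
every graph listed in the assertions graph must resolve in the store, every
assay output must be one of the document's description graphs, and the
partonomy must have a unique root and no cycles.

Severities are the package's own split, since the model mandates schemes but
not severities: structural defects are errors; a part with multiple parents
and a description graph not covered by any assay are warnings, because
descriptions drawn from several specimens may legitimately have partial
provenance and the partonomy is drawn as a tree but not forced to be one.

The schemes are tuned so that deleting *any required statement* from any
builder output flips document validation to failing — the test suite checks
this exhaustively over the worked example. Statements the schemes
deliberately tolerate losing are exactly: free-text and title literals,
date literals, specimen labels in history graphs, and redundant assay output
links (an assay must keep at least one output, but dropping one of several
leaves a structurally valid, if less documented, description — it degrades
to the unreferenced-provenance warning).

## The generator, and what passing tests do not show

`generate_description()` emulates one complete description document: a
random partonomy grown by uniform attachment (each new part picks a uniform
parent among nodes above the depth cap), per-part texture and measurement
annotations at rates 0.3 and 0.4, measurement values drawn log-uniformly
(volumes over 0.01–10 ml, lengths over 0.1–100 of the sampled metre-based
unit) so values span realistic orders of magnitude, one collection, a
specimen history forking with probability 0.25, and assays that partition
the description graphs uniformly among specimens. One seeded RNG stream
drives both structure and values, so a seed fixes the store byte-for-byte;
the caller's RNG state is saved and restored.

These defaults are what the package's checks run under. Problem sizes used
by the shipped checks: ~100 random configurations with 1–10 parts for
losslessness, 15 for query-oracle equivalence, 12 for view algebra, trees of
up to 1,000 parts for partonomy recovery, and the exhaustive
single-statement deletion sweep (80 required statements) on the worked
example.

What the generator does *not* emulate, and hence what green checks do not
demonstrate: real descriptions have far deeper and more heterogeneous
partonomies, free-text-heavy sections, multiple documents sharing specimens,
revised or conflicting observations, and terminology outside the bundled
catalog. The generator also never produces blank nodes or malformed shapes
except through explicit mutation, so validation performance on arbitrary
third-party RDF is untested beyond the parser's subset checks.

## Numerical and representational choices

* Float literals are serialized with `%.15g`, enough to round-trip doubles
  in practice while keeping lexical forms stable across platforms; values
  must be finite (NaN/Inf are rejected at record construction).
* Statement sets are canonicalized (sorted, deduplicated) on every graph
  construction and union; equality is set equality, never order-sensitive.
* Dates are single ISO-8601 date literals and places single labeled
  instances; the model asks only for "where and when".
* Labels are plain literals by default, with optional language tags.
* TriG and N-Quads cover exactly the blank-node-free, absolute-IRI subset
  the package emits; the parser reports line numbers on malformed input. A
  graph whose class cannot be recovered on read (no type triple for it in
  the document or assertions graph) is typed `unclassified` and flagged by
  the validator as a warning rather than rejected.
* The document graph registers the assertions graph by *typing* its IRI
  plus one explicit link predicate; the lookup query needs only the type
  triple. This resolves the unspecified document↔assertions linkage in the
  way that keeps the query template a pure pattern match.
* The worked example (`worked_example()`) uses three parts — the organism
  root plus the head (bearing the 0.25 ml volume) and the thorax (bearing
  the rough surface texture) — so that the description union is a single
  connected component; its texture is attached to the thorax part itself,
  a deliberate simplification of modeling a separate anatomical-surface
  individual.
* The specimen history gets its own named-graph class even though the model
  leaves it to "a separate specimen document"; a uniform storage model means
  every statement in the store lives in a typed, validated named graph.

## Limitations

No OWL reasoning or entailment is performed anywhere: `rdf:type` statements
are compared literally, and "subclass of texture" is approximated by the
catalog's family tags rather than by ontology subsumption. There is no
SPARQL endpoint; the query templates are library operations (and a CLI).
Class-based phenotype representations (EQ-style TBox expressions) are out of
scope by design — they are exactly the representation whose fragmentation
the instance-based model exists to avoid. The bundled catalog is a snapshot:
IRIs for a handful of convenience classes (person, place, live trap,
microscopy assay) are project-local, and production deployments would
register their institution's terms instead.
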