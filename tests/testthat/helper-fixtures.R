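# Hand-wired small description used where statement counts are enumerated by
# hand: four parts (root + three children), one texture, one volume
# measurement, a collection, a one-step history and one assay covering all
# description graphs.

small_description <- function(seed = 5L) {
  minter <- iri_minter("https://test.example.org/", seed)
  root <- make_instance("organism", "whole organism", minter)
  kids <- list(make_instance("head", "the head", minter),
               make_instance("thorax", "the thorax", minter),
               make_instance("abdomen", "the abdomen", minter))
  edges <- lapply(kids, function(k) list(parent = root, child = k))
  qualities <- list(quality_record(kids[[2]], "rough",
                                   "anatomical-surface-texture"))
  measurements <- list(measurement_record(kids[[1]], "volume", 0.25,
                                          "milliliter",
                                          "anatomical-structure-volume"))
  material <- make_instance("material-entity", "raw material", minter)
  spec_a <- make_instance("specimen", "specimen A", minter)
  collection <- collection_record(
    make_instance("specimen-collection-process", NULL, minter),
    material, spec_a, date = "2019-05-04")
  spec_b <- make_instance("specimen", "specimen B", minter)
  steps <- list(processing_step(
    make_instance("material-processing", NULL, minter),
    list(spec_a), list(spec_b)))
  assays <- list(list(assay = make_instance("microscopy-assay", NULL, minter),
                      specimen = spec_b, graphs = 1:6))
  compose_document(document_metadata(), root, edges, qualities, measurements,
                   collection, steps, assays, minter)
}

clone_store <- function(store) {
  out <- quad_store()
  for (iri in graph_iris(store)) add_graph(out, get_graph(store, iri))
  out
}

# replace graph `iri` with a copy lacking statement row `i`
delete_statement <- function(store, iri, i) {
  out <- clone_store(store)
  g <- get_graph(store, iri)
  add_graph(out, named_graph(iri, g$ng_class, g$statements[-i, , drop = FALSE]),
            replace = TRUE)
  out
}

quad_keys <- function(store) {
  q <- quads(store)
  paste(q$graph, q$s, q$p, q$o, q$o_kind,
        ifelse(is.na(q$dt), "", q$dt), ifelse(is.na(q$lang), "", q$lang))
}

# statements whose deletion the schemes deliberately tolerate (free text,
# titles, dates, history labels, redundant assay outputs)
is_optional_statement <- function(g, row) {
  row$p %in% c(PT[["has_free_text"]], PT[["has_title"]], PT[["has_date"]]) ||
    (g$ng_class == "specimen-history" && row$p == PT[["rdfs_label"]]) ||
    (g$ng_class == "assay-data" && row$p == PT[["has_specified_output"]] &&
       sum(g$statements$p == PT[["has_specified_output"]]) > 1L)
}
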