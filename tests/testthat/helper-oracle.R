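# Brute-force quad-scan oracle: re-implements the query templates as plain
# scans over the flat quad table, independently of the store's query
# operations, for template-vs-oracle equivalence checks.

PT <- default_predicates()

oracle_scan <- function(store, s = NULL, p = NULL, o = NULL, o_kind = "iri") {
  q <- quads(store)
  keep <- rep(TRUE, nrow(q))
  if (!is.null(s)) keep <- keep & q$s == s
  if (!is.null(p)) keep <- keep & q$p == p
  if (!is.null(o)) keep <- keep & q$o == o & q$o_kind == o_kind
  q[keep, , drop = FALSE]
}

oracle_find_graphs <- function(store, s = NULL, p = NULL, o = NULL,
                               o_kind = "iri") {
  sort(unique(oracle_scan(store, s, p, o, o_kind)$graph))
}

oracle_one <- function(x) {
  stopifnot(length(unique(x)) == 1L)
  unique(x)
}

oracle_locate_document <- function(store, doc) {
  oracle_one(oracle_scan(store, s = doc, p = PT[["rdf_type"]],
                         o = term("iao-document")$iri)$graph)
}

oracle_locate_assertions <- function(store, dg) {
  q <- oracle_scan(store, p = PT[["rdf_type"]], o = term("assertions")$iri)
  oracle_one(q$s[q$graph == dg])
}

oracle_locate_anatomy <- function(store, ag) {
  q <- oracle_scan(store, p = PT[["rdf_type"]], o = term("instance-anatomy")$iri)
  oracle_one(q$s[q$graph == ag])
}

# statements of all graphs attached to `owner` in the assertions graph,
# optionally class-filtered by a type triple in the assertions graph
oracle_union <- function(store, owner, ag, class_key = NULL) {
  q <- quads(store)
  inag <- q[q$graph == ag, , drop = FALSE]
  gs <- inag$o[inag$s == owner & inag$p == PT[["has_part"]] &
                 inag$o_kind == "iri"]
  if (!is.null(class_key)) {
    typed <- inag$s[inag$p == PT[["rdf_type"]] &
                      inag$o == term(class_key)$iri]
    gs <- intersect(gs, typed)
  }
  sub <- q[q$graph %in% gs, c("s", "p", "o", "o_kind", "dt", "lang"),
           drop = FALSE]
  st_union(sub)
}

oracle_methods_section <- function(store, dg) {
  q <- oracle_scan(store, p = PT[["rdf_type"]],
                   o = term("methods-section")$iri)
  oracle_one(q$s[q$graph == dg])
}
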