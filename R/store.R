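# Named graphs and the quad store. A named graph is the unit of
# fragmentation: a non-empty set of triples identified by its own IRI and
# typed by a named-graph class. Adding the graph IRI to each triple yields
# quads; the store answers pattern queries over those quads.

#' Construct a named graph
#'
#' @param iri the graph's own IRI.
#' @param ng_class catalog key of the named-graph class (e.g. `"parthood"`).
#' @param statements a non-empty statement data frame; duplicates collapse
#'   (set semantics).
#' @return object of class `named_graph`.
#' @export
named_graph <- function(iri, ng_class, statements) {
  assert_iri(iri, "graph IRI")
  if (!ng_class %in% ng_class_keys()) {
    akg_stop("akg_catalog_error",
             "'%s' is not a registered named-graph class", ng_class)
  }
  st <- st_union(statements)
  if (nrow(st) == 0L) {
    akg_stop("akg_scheme_error", "a named graph must contain statements")
  }
  structure(list(iri = iri, ng_class = ng_class, statements = st),
            class = "named_graph")
}

#' @export
print.named_graph <- function(x, ...) {
  cat(sprintf("<named_graph> %s\n  class: %s\n  statements: %d\n",
              x$iri, x$ng_class, nrow(x$statements)))
  invisible(x)
}

#' Create an empty quad store
#'
#' The store holds the named graphs of one or more description documents,
#' keyed by graph IRI, and answers triple-pattern queries over the resulting
#' quads.
#'
#' @return object of class `quad_store`.
#' @export
quad_store <- function() {
  structure(list(graphs = new.env(parent = emptyenv())), class = "quad_store")
}

#' Add a named graph to a store
#' @param store a [quad_store()].
#' @param g a [named_graph()].
#' @param replace replace an existing graph with the same IRI instead of
#'   raising a collision error.
#' @return the store, invisibly (the store is modified in place).
#' @export
add_graph <- function(store, g, replace = FALSE) {
  stopifnot(inherits(store, "quad_store"), inherits(g, "named_graph"))
  if (!replace && !is.null(store$graphs[[g$iri]])) {
    akg_stop("akg_collision_error", "graph IRI already in store: %s", g$iri)
  }
  assign(g$iri, g, envir = store$graphs)
  invisible(store)
}

#' Retrieve a named graph by IRI
#' @param store a [quad_store()].
#' @param iri graph IRI.
#' @return the [named_graph()].
#' @export
get_graph <- function(store, iri) {
  g <- store$graphs[[iri]]
  if (is.null(g)) {
    akg_stop("akg_dangling_error", "no graph with IRI %s in store", iri)
  }
  g
}

#' IRIs of all graphs in a store, lexicographically sorted
#' @param store a [quad_store()].
#' @return character vector.
#' @export
graph_iris <- function(store) {
  sort(ls(store$graphs), method = "radix")
}

#' All quads in a store as a data frame
#' @param store a [quad_store()].
#' @return statement data frame with an extra `graph` column.
#' @export
quads <- function(store) {
  iris <- graph_iris(store)
  qs <- lapply(iris, function(i) {
    g <- store$graphs[[i]]
    cbind(g$statements, graph = i, stringsAsFactors = FALSE)
  })
  if (length(qs) == 0L) return(cbind(statements(), graph = character()))
  out <- do.call(rbind, qs)
  rownames(out) <- NULL
  out
}

#' @export
print.quad_store <- function(x, ...) {
  iris <- graph_iris(x)
  n_st <- sum(vapply(iris, function(i) nrow(x$graphs[[i]]$statements), 0L))
  cat(sprintf("<quad_store> %d named graphs, %d quads\n", length(iris), n_st))
  invisible(x)
}

## Triple patterns and the query templates -----------------------------------

#' Create a triple pattern
#'
#' `NULL` positions are wildcards; at least one position must be bound. The
#' object may be an IRI (the default) or a literal.
#'
#' @param s,p subject / predicate IRI or `NULL`.
#' @param o object IRI, literal lexical form, or `NULL`.
#' @param o_kind `"iri"` or `"literal"`; only consulted when `o` is bound.
#' @return object of class `triple_pattern`.
#' @export
triple_pattern <- function(s = NULL, p = NULL, o = NULL, o_kind = "iri") {
  if (is.null(s) && is.null(p) && is.null(o)) {
    akg_stop("akg_pattern_error", "at least one pattern position must be bound")
  }
  structure(list(s = s, p = p, o = o, o_kind = o_kind),
            class = "triple_pattern")
}

match_pattern <- function(st, pat) {
  keep <- rep(TRUE, nrow(st))
  if (!is.null(pat$s)) keep <- keep & st$s == pat$s
  if (!is.null(pat$p)) keep <- keep & st$p == pat$p
  if (!is.null(pat$o)) keep <- keep & st$o == pat$o & st$o_kind == pat$o_kind
  keep
}

#' Graphs whose statement set matches a triple pattern
#'
#' The first step of every query template: given a triple known to sit in a
#' graph of interest, find the named graph(s) that contain it.
#'
#' @param store a [quad_store()].
#' @param pattern a [triple_pattern()].
#' @return character vector of graph IRIs, lexicographically sorted.
#' @export
find_graphs_containing <- function(store, pattern) {
  stopifnot(inherits(pattern, "triple_pattern"))
  iris <- graph_iris(store)
  hit <- vapply(iris, function(i) {
    any(match_pattern(store$graphs[[i]]$statements, pattern))
  }, logical(1))
  iris[hit]
}

locate_unique <- function(store, iris, what) {
  if (length(iris) == 0L) {
    akg_stop("akg_notfound_error", "no %s found", what)
  }
  if (length(iris) > 1L) {
    akg_stop("akg_ambiguity_error", "%d candidate %ss found", length(iris), what)
  }
  iris
}

#' Locate the document named graph of a document
#'
#' Searches for the unique named graph containing the triple
#' `(doc, rdf:type, iao:document)` — the entry point into a description
#' document.
#'
#' @param store a [quad_store()].
#' @param doc IRI of the `iao:document` instance.
#' @param pt predicate table.
#' @return the document graph's IRI.
#' @export
locate_document_graph <- function(store, doc, pt = default_predicates()) {
  hits <- find_graphs_containing(
    store, triple_pattern(s = doc, p = pt[["rdf_type"]],
                          o = term("iao-document")$iri))
  locate_unique(store, hits, "document graph")
}

#' Locate the assertions named graph registered in a document graph
#'
#' @param store a [quad_store()].
#' @param document_graph IRI of the document named graph.
#' @param pt predicate table.
#' @return the assertions graph's IRI.
#' @export
locate_assertions_graph <- function(store, document_graph,
                                    pt = default_predicates()) {
  st <- get_graph(store, document_graph)$statements
  hits <- st$s[st$p == pt[["rdf_type"]] & st$o_kind == "iri" &
                 st$o == term("assertions")$iri]
  locate_unique(store, sort(unique(hits), method = "radix"),
                "assertions graph")
}

#' Locate the instance anatomy within an assertions graph
#'
#' @param store a [quad_store()].
#' @param assertions_graph IRI of the assertions named graph.
#' @param pt predicate table.
#' @return the IRI of the individual typed `instance anatomy`.
#' @export
locate_instance_anatomy <- function(store, assertions_graph,
                                    pt = default_predicates()) {
  st <- get_graph(store, assertions_graph)$statements
  hits <- st$s[st$p == pt[["rdf_type"]] & st$o_kind == "iri" &
                 st$o == term("instance-anatomy")$iri]
  locate_unique(store, sort(unique(hits), method = "radix"),
                "instance anatomy")
}

#' Union of named graphs
#'
#' Set-union of the statements of the listed graphs; duplicates collapse and
#' graph provenance is dropped (use [find_graphs_containing()] when
#' provenance is needed).
#'
#' @param store a [quad_store()].
#' @param iris graph IRIs; all must resolve.
#' @return statement data frame.
#' @export
union_graphs <- function(store, iris) {
  do.call(st_union, lapply(iris, function(i) get_graph(store, i)$statements))
}

# Graph IRIs attached via has_part to `owner` inside the assertions graph,
# optionally filtered to one named-graph class; sorted.
attached_graphs <- function(store, owner, assertions_graph, pt,
                            ng_class = NULL) {
  st <- get_graph(store, assertions_graph)$statements
  gs <- st$o[st$s == owner & st$p == pt[["has_part"]] & st$o_kind == "iri"]
  if (!is.null(ng_class)) {
    cls <- term(ng_class)$iri
    typed <- st$s[st$p == pt[["rdf_type"]] & st$o_kind == "iri" & st$o == cls]
    gs <- intersect(gs, typed)
  }
  sort(unique(gs), method = "radix")
}

#' Union of all parthood named graphs of a description
#'
#' Resolves, within the assertions graph, the named graphs that are parts of
#' the instance anatomy, filters them to the parthood named-graph class, and
#' returns the union of their statements: the partonomy backbone with each
#' part's class affiliation and label.
#'
#' @param store a [quad_store()].
#' @param anatomy IRI of the instance anatomy.
#' @param assertions_graph IRI of the assertions named graph.
#' @param pt predicate table.
#' @return statement data frame.
#' @export
parthood_union <- function(store, anatomy, assertions_graph,
                           pt = default_predicates()) {
  union_graphs(store, attached_graphs(store, anatomy, assertions_graph, pt,
                                      ng_class = "parthood"))
}

#' Union of all description named graphs: the Anatomy Knowledge Graph
#'
#' The union over every named graph that is a part of the instance anatomy,
#' with no class filter — the complete instance-level morphological
#' description recorded in the document.
#'
#' @inheritParams parthood_union
#' @return statement data frame.
#' @export
description_union <- function(store, anatomy, assertions_graph,
                              pt = default_predicates()) {
  union_graphs(store, attached_graphs(store, anatomy, assertions_graph, pt))
}

#' Union of all metadata named graphs attached to the methods section
#'
#' @param store a [quad_store()].
#' @param methods_section IRI of the document's methods-section instance.
#' @param assertions_graph IRI of the assertions named graph.
#' @param pt predicate table.
#' @return statement data frame.
#' @export
metadata_union <- function(store, methods_section, assertions_graph,
                           pt = default_predicates()) {
  union_graphs(store, attached_graphs(store, methods_section,
                                      assertions_graph, pt))
}

## Partonomy extraction ------------------------------------------------------

#' Extract the partonomy from a parthood union
#'
#' Reads a statement set (normally the output of [parthood_union()]) into a
#' rooted tree: `has_part` statements give the edges, `rdf:type` the class
#' affiliation and `rdfs:label` the label of each part. The root is the
#' unique node without an incoming `has_part` edge.
#'
#' @param st statement data frame.
#' @param pt predicate table.
#' @return object of class `partonomy`: list with `root`, `edges`
#'   (data frame `parent`, `child`), `labels` and `classes` (named character
#'   vectors keyed by part IRI).
#' @export
extract_partonomy <- function(st, pt = default_predicates()) {
  hp <- st[st$p == pt[["has_part"]] & st$o_kind == "iri", , drop = FALSE]
  ty <- st[st$p == pt[["rdf_type"]] & st$o_kind == "iri", , drop = FALSE]
  lb <- st[st$p == pt[["rdfs_label"]] & st$o_kind == "literal", , drop = FALSE]
  nodes <- sort(unique(c(hp$s, hp$o, ty$s, lb$s)), method = "radix")
  roots <- setdiff(nodes, hp$o)
  if (length(roots) != 1L) {
    akg_stop("akg_partonomy_error",
             "malformed partonomy: %d root candidates", length(roots))
  }
  # cycle check by iterated leaf-stripping (Kahn)
  parents <- hp$s; children <- hp$o
  indeg <- table(factor(children, levels = nodes))
  queue <- nodes[indeg == 0L]; seen <- 0L
  indeg <- as.integer(indeg); names(indeg) <- nodes
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in children[parents == v]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes)) {
    akg_stop("akg_cycle_error", "cycle detected in partonomy")
  }
  labels <- stats::setNames(lb$o, lb$s)
  classes <- stats::setNames(ty$o, ty$s)
  structure(list(root = roots,
                 edges = data.frame(parent = hp$s, child = hp$o,
                                    stringsAsFactors = FALSE),
                 labels = labels[nodes[nodes %in% names(labels)]],
                 classes = classes[nodes[nodes %in% names(classes)]]),
            class = "partonomy")
}

#' @export
print.partonomy <- function(x, ...) {
  cat(sprintf("<partonomy> %d parts, %d edges\n  root: %s (%s)\n",
              length(unique(c(x$edges$parent, x$edges$child, x$root))),
              nrow(x$edges), x$root,
              if (x$root %in% names(x$labels)) x$labels[[x$root]] else "?"))
  invisible(x)
}
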