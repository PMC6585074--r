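# Data views: named selections of named-graph classes, optionally filtered
# (e.g. metre-based measurement units), resolved per document as the union
# of the matching graphs. First-level views name a single class; combined
# views name several; filtered views additionally constrain the graphs'
# unit instances.

#' Units counted as metre-based
#'
#' Catalog keys of length units used by the default `lengths-and-distances`
#' view filter; extend via [register_term()] with family `"metre-unit"`.
#'
#' @return character vector of unit class IRIs.
#' @export
metre_based_units <- function() {
  cat_df <- term_catalog()
  cat_df$iri[cat_df$family == "metre-unit"]
}

#' Define a data view
#'
#' @param name unique view name.
#' @param ng_classes non-empty character vector of named-graph class keys.
#' @param unit_filter optional predicate `function(unit_class_iri) -> logical`
#'   applied to the class of each graph's unit instance; a graph passes a
#'   filtered view only if it carries at least one unit satisfying the
#'   filter.
#' @param description free-text description of the question the view answers.
#' @param register register the view by name in the package view registry so
#'   the command-line interface can invoke it.
#' @return object of class `data_view`.
#' @export
#' @examples
#' define_view("parthood-view", "parthood", register = FALSE)
define_view <- function(name, ng_classes, unit_filter = NULL,
                        description = "", register = TRUE) {
  if (length(ng_classes) == 0L) {
    akg_stop("akg_view_error", "a view needs at least one named-graph class")
  }
  bad <- setdiff(ng_classes, ng_class_keys())
  if (length(bad) > 0L) {
    akg_stop("akg_catalog_error", "unknown named-graph classes: %s",
             paste(bad, collapse = ", "))
  }
  v <- structure(list(name = name, ng_classes = unique(ng_classes),
                      unit_filter = unit_filter, description = description),
                 class = "data_view")
  if (register) {
    reg <- akg_state()$views
    if (!is.null(reg[[name]])) {
      akg_stop("akg_view_error", "a view named '%s' is already registered", name)
    }
    assign(name, v, envir = reg)
  }
  v
}

builtin_views <- function() {
  meas <- c("anatomical-structure-volume", "anatomical-structure-length")
  metre <- function(unit_iri) unit_iri %in% metre_based_units()
  list(
    structure(list(name = "parthood-view", ng_classes = "parthood",
                   unit_filter = NULL,
                   description = "all direct parthood relations"),
              class = "data_view"),
    structure(list(name = "general-measurements", ng_classes = meas,
                   unit_filter = NULL,
                   description = "all measurement data of a document"),
              class = "data_view"),
    structure(list(name = "lengths-and-distances", ng_classes = meas,
                   unit_filter = metre,
                   description = "metre-based measurements only"),
              class = "data_view")
  )
}

#' Look up a registered view by name
#' @param name view name.
#' @return the `data_view`.
#' @export
get_view <- function(name) {
  v <- akg_state()$views[[name]]
  if (is.null(v)) akg_stop("akg_view_error", "no view named '%s'", name)
  v
}

#' Names of all registered views
#' @return character vector, sorted.
#' @export
view_names <- function() sort(ls(akg_state()$views), method = "radix")

graph_passes_filter <- function(g, flt, pt) {
  if (is.null(flt)) return(TRUE)
  st <- g$statements
  units <- st$o[st$p == pt[["has_unit"]] & st$o_kind == "iri"]
  if (length(units) == 0L) return(FALSE)
  cls <- st$o[st$p == pt[["rdf_type"]] & st$s %in% units & st$o_kind == "iri"]
  any(vapply(cls, flt, logical(1)))
}

#' Resolve a data view against one document
#'
#' Collects the document's named graphs (description and metadata graphs
#' wired through the assertions graph) whose class is in the view's class
#' set, applies the unit filter if the view carries one, and returns the
#' union of their statements.
#'
#' @param store a [quad_store()].
#' @param document IRI of the `iao:document` instance.
#' @param view a `data_view` or the name of a registered view.
#' @param pt predicate table.
#' @return statement data frame.
#' @export
resolve_view <- function(store, document, view, pt = default_predicates()) {
  if (is.character(view)) view <- get_view(view)
  stopifnot(inherits(view, "data_view"))
  dg <- locate_document_graph(store, document, pt)
  ag <- locate_assertions_graph(store, dg, pt)
  anatomy <- locate_instance_anatomy(store, ag, pt)
  methods_sec <- locate_section(store, dg, "methods-section", pt)
  candidates <- unique(c(attached_graphs(store, anatomy, ag, pt),
                         attached_graphs(store, methods_sec, ag, pt)))
  keep <- vapply(candidates, function(iri) {
    g <- get_graph(store, iri)
    g$ng_class %in% view$ng_classes && graph_passes_filter(g, view$unit_filter, pt)
  }, logical(1))
  union_graphs(store, sort(candidates[keep], method = "radix"))
}

#' Resolve a data view against a set of documents
#' @param store a [quad_store()].
#' @param documents character vector of document IRIs.
#' @param view a `data_view` or registered view name.
#' @param pt predicate table.
#' @return statement data frame: the union of the per-document resolutions.
#' @export
resolve_view_multi <- function(store, documents, view,
                               pt = default_predicates()) {
  do.call(st_union, lapply(documents, function(d) {
    resolve_view(store, d, view, pt)
  }))
}

#' @export
print.data_view <- function(x, ...) {
  cat(sprintf("<data_view> %s: {%s}%s\n", x$name,
              paste(x$ng_classes, collapse = ", "),
              if (is.null(x$unit_filter)) "" else " + unit filter"))
  invisible(x)
}
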