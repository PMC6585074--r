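# Builders: one constructor per named-graph class. Each descriptive
# statement (a parthood edge, a quality, a measurement) goes into its own
# named graph; metadata processes (assay, collection, specimen history) each
# get a graph of their own class. Builders are scheme-exact: their output
# passes the class's validation scheme with no warnings.

SECTION_KEYS <- c("abstract", "author-list", "introduction",
                  "methods-section", "results-section", "discussion-section",
                  "conclusion-section", "references-section")

fmt_float <- function(x) sprintf("%.15g", x)

#' Document metadata
#'
#' @param title document title ("" for none).
#' @param sections named list/vector mapping section keys (a subset of
#'   `abstract`, `author-list`, `introduction`, `methods-section`,
#'   `results-section`, `discussion-section`, `conclusion-section`,
#'   `references-section`) to free-text strings (`""` for a section with no
#'   text). The methods and results sections are mandatory.
#' @return object of class `document_metadata`.
#' @export
document_metadata <- function(title = "",
                              sections = stats::setNames(
                                rep("", length(SECTION_KEYS)), SECTION_KEYS)) {
  sections <- as.list(sections)
  bad <- setdiff(names(sections), SECTION_KEYS)
  if (length(bad) > 0L) {
    akg_stop("akg_scheme_error", "unknown section keys: %s",
             paste(bad, collapse = ", "))
  }
  if (!all(c("methods-section", "results-section") %in% names(sections))) {
    akg_stop("akg_scheme_error",
             "document metadata must include methods and results sections")
  }
  structure(list(title = title, sections = sections),
            class = "document_metadata")
}

mint_graph_iri <- function(minter, ng_class) {
  mint_iri(minter, paste0("g-", ng_class))
}

#' Build the document named graph
#'
#' Relates an `iao:document` instance to one instance per document section
#' (abstract, author list, ..., references), attaches free text to sections
#' that have any, and registers the document's assertions named graph by
#' typing its IRI — which is the triple the assertions-lookup query template
#' relies on.
#'
#' @param meta a [document_metadata()].
#' @param doc an [make_instance()] typed `iao-document`.
#' @param assertions_iri IRI reserved for the assertions named graph.
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return a [named_graph()] of class `document`; the section instances are
#'   attached as `attr(, "sections")` (a named list keyed by section key) so
#'   callers can wire the assertions graph to the methods and results
#'   sections.
#' @export
build_document_graph <- function(meta, doc, assertions_iri, minter,
                                 pt = default_predicates()) {
  stopifnot(inherits(meta, "document_metadata"), inherits(doc, "instance"))
  if (is.na(doc$class_ref$key) || doc$class_ref$key != "iao-document") {
    akg_stop("akg_scheme_error", "doc must be an instance of iao-document")
  }
  assert_iri(assertions_iri, "assertions graph IRI")
  st <- st_iri(doc$iri, pt[["rdf_type"]], doc$class_ref$iri)
  if (nzchar(meta$title)) {
    st <- rbind(st, st_literal(doc$iri, pt[["has_title"]], meta$title))
  }
  sections <- list()
  for (key in names(meta$sections)) {
    sec <- make_instance(key, NULL, minter)
    sections[[key]] <- sec
    st <- rbind(st,
                st_iri(sec$iri, pt[["rdf_type"]], sec$class_ref$iri),
                st_iri(doc$iri, pt[["has_part"]], sec$iri))
    text <- meta$sections[[key]]
    if (!is.null(text) && nzchar(text)) {
      st <- rbind(st, st_literal(sec$iri, pt[["has_free_text"]], text))
    }
  }
  st <- rbind(st,
              st_iri(assertions_iri, pt[["rdf_type"]], term("assertions")$iri),
              st_iri(doc$iri, pt[["has_assertions_graph"]], assertions_iri))
  g <- named_graph(mint_graph_iri(minter, "document"), "document", st)
  attr(g, "sections") <- sections
  g
}

#' Build the parthood named graph of the partonomy root
#'
#' The root's graph records only its class affiliation and its mandatory
#' human-readable label — the root has no parent.
#'
#' @param root an [make_instance()] with a label.
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return a [named_graph()] of class `parthood` with exactly 2 statements.
#' @export
build_root_parthood_graph <- function(root, minter,
                                      pt = default_predicates()) {
  stopifnot(inherits(root, "instance"))
  if (is.na(root$label)) {
    akg_stop("akg_scheme_error", "partonomy root must have a label")
  }
  st <- rbind(st_iri(root$iri, pt[["rdf_type"]], root$class_ref$iri),
              st_literal(root$iri, pt[["rdfs_label"]], root$label))
  named_graph(mint_graph_iri(minter, "parthood"), "parthood", st)
}

#' Build the parthood named graph of one part
#'
#' One parthood edge per graph: the child's class affiliation, its label and
#' the `bfo:has part` relation from its direct parent.
#'
#' @param parent,child [make_instance()] objects; `child` must carry a label.
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return a [named_graph()] of class `parthood` with exactly 3 statements.
#' @export
build_parthood_graph <- function(parent, child, minter,
                                 pt = default_predicates()) {
  stopifnot(inherits(parent, "instance"), inherits(child, "instance"))
  if (parent$iri == child$iri) {
    akg_stop("akg_cycle_error", "an entity cannot be a part of itself")
  }
  if (is.na(child$label)) {
    akg_stop("akg_scheme_error", "part must have a label")
  }
  st <- rbind(st_iri(child$iri, pt[["rdf_type"]], child$class_ref$iri),
              st_literal(child$iri, pt[["rdfs_label"]], child$label),
              st_iri(parent$iri, pt[["has_part"]], child$iri))
  named_graph(mint_graph_iri(minter, "parthood"), "parthood", st)
}

#' Quality annotation record
#'
#' @param bearer the anatomical instance bearing the quality.
#' @param quality_class a `term_ref` or catalog key of a quality class whose
#'   catalog family matches the category (e.g. a texture subclass for the
#'   surface-texture category).
#' @param category catalog key of the named-graph class to store the
#'   annotation in (e.g. `"anatomical-surface-texture"`).
#' @return object of class `quality_record`.
#' @export
quality_record <- function(bearer, quality_class, category) {
  stopifnot(inherits(bearer, "instance"))
  if (is.character(quality_class)) quality_class <- term(quality_class)
  if (!category %in% ng_class_keys()) {
    akg_stop("akg_catalog_error",
             "quality category '%s' is not a registered named-graph class",
             category)
  }
  cat_df <- term_catalog()
  fam <- cat_df$family[cat_df$key == category]
  qfam <- cat_df$family[cat_df$iri == quality_class$iri]
  if (length(qfam) > 0L && nzchar(fam) && !fam %in% qfam) {
    akg_stop("akg_catalog_error",
             "quality class '%s' does not belong to family '%s'",
             quality_class$label, fam)
  }
  structure(list(bearer = bearer, quality_class = quality_class,
                 category = category), class = "quality_record")
}

#' Build a quality named graph
#'
#' Relates the bearer to a freshly minted instance of the quality class: two
#' statements, one descriptive proposition.
#'
#' @param rec a [quality_record()].
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return a [named_graph()] of the category's class with 2 statements.
#' @export
build_quality_graph <- function(rec, minter, pt = default_predicates()) {
  stopifnot(inherits(rec, "quality_record"))
  q <- make_instance(rec$quality_class, NULL, minter)
  st <- rbind(st_iri(rec$bearer$iri, pt[["has_quality"]], q$iri),
              st_iri(q$iri, pt[["rdf_type"]], q$class_ref$iri))
  named_graph(mint_graph_iri(minter, rec$category), rec$category, st)
}

#' Measurement record
#'
#' @param bearer the measured anatomical instance.
#' @param quality_class measured quality (`term_ref` or catalog key, e.g.
#'   `"volume"`).
#' @param value finite numeric measurement value.
#' @param unit unit class (`term_ref` or catalog key) from the units
#'   ontology namespace.
#' @param category catalog key of the measurement named-graph class (e.g.
#'   `"anatomical-structure-volume"`).
#' @return object of class `measurement_record`.
#' @export
measurement_record <- function(bearer, quality_class, value, unit, category) {
  stopifnot(inherits(bearer, "instance"))
  if (is.character(quality_class)) quality_class <- term(quality_class)
  if (is.character(unit)) unit <- term(unit)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    akg_stop("akg_value_error", "measurement value must be a finite number")
  }
  if (unit$prefix != "uo") {
    akg_stop("akg_catalog_error",
             "measurement unit must come from the units ontology namespace")
  }
  if (!category %in% ng_class_keys()) {
    akg_stop("akg_catalog_error",
             "measurement category '%s' is not a registered named-graph class",
             category)
  }
  structure(list(bearer = bearer, quality_class = quality_class,
                 value = value, unit = unit, category = category),
            class = "measurement_record")
}

#' Build a measurement named graph
#'
#' Five statements: the bearer's quality instance, its class affiliation,
#' the measured value as a float literal, and a typed unit instance.
#'
#' @param rec a [measurement_record()].
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return a [named_graph()] of the category's class with 5 statements.
#' @export
build_measurement_graph <- function(rec, minter, pt = default_predicates()) {
  stopifnot(inherits(rec, "measurement_record"))
  q <- make_instance(rec$quality_class, NULL, minter)
  u <- make_instance(rec$unit, NULL, minter)
  st <- rbind(
    st_iri(rec$bearer$iri, pt[["has_quality"]], q$iri),
    st_iri(q$iri, pt[["rdf_type"]], q$class_ref$iri),
    st_literal(q$iri, pt[["has_value"]], fmt_float(rec$value), dt = XSD_FLOAT),
    st_iri(q$iri, pt[["has_unit"]], u$iri),
    st_iri(u$iri, pt[["rdf_type"]], u$class_ref$iri))
  named_graph(mint_graph_iri(minter, rec$category), rec$category, st)
}

process_optionals <- function(subject, rec, pt) {
  st <- statements()
  roles <- c(agent = "has_agent", device = "has_device",
             protocol = "has_protocol", place = "has_place")
  for (r in names(roles)) {
    x <- rec[[r]]
    if (!is.null(x)) {
      st <- rbind(st,
                  st_iri(x$iri, pt[["rdf_type"]], x$class_ref$iri),
                  st_iri(subject, pt[[roles[[r]]]], x$iri))
    }
  }
  if (!is.null(rec$date)) {
    st <- rbind(st, st_literal(subject, pt[["has_date"]],
                               as.character(rec$date), dt = XSD_DATE))
  }
  st
}

#' Assay (observation process) record
#'
#' @param assay instance of an assay class (e.g. `"microscopy-assay"` or
#'   `"assay"`).
#' @param input_specimen the observed specimen instance (exactly one).
#' @param output_graphs non-empty character vector of IRIs of the description
#'   named graphs produced by this observation.
#' @param agent,device,protocol,place optional instances.
#' @param date optional ISO date (string or `Date`).
#' @param extra_inputs optional list of substance instances used during the
#'   assay, recorded as additional specified inputs.
#' @return object of class `assay_record`.
#' @export
assay_record <- function(assay, input_specimen, output_graphs,
                         agent = NULL, device = NULL, protocol = NULL,
                         place = NULL, date = NULL, extra_inputs = list()) {
  stopifnot(inherits(assay, "instance"), inherits(input_specimen, "instance"))
  if (length(output_graphs) == 0L) {
    akg_stop("akg_scheme_error", "an assay must specify at least one output graph")
  }
  assert_iri(output_graphs, "output graph IRI")
  structure(list(assay = assay, input_specimen = input_specimen,
                 output_graphs = output_graphs, agent = agent,
                 device = device, protocol = protocol, place = place,
                 date = date, extra_inputs = extra_inputs),
            class = "assay_record")
}

#' Build an assay data named graph
#'
#' The assay instance takes the central position: the specimen is its
#' specified input, each description named graph produced by the observation
#' is a specified output, and who/where/when/how is attached through typed
#' agent, device, protocol and place instances and a date literal.
#'
#' @param rec an [assay_record()].
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return a [named_graph()] of class `assay-data`.
#' @export
build_assay_graph <- function(rec, minter, pt = default_predicates()) {
  stopifnot(inherits(rec, "assay_record"))
  a <- rec$assay$iri
  st <- rbind(st_iri(a, pt[["rdf_type"]], rec$assay$class_ref$iri),
              st_iri(a, pt[["has_specified_input"]], rec$input_specimen$iri),
              st_iri(a, pt[["has_specified_output"]], rec$output_graphs))
  for (x in rec$extra_inputs) {
    st <- rbind(st,
                st_iri(x$iri, pt[["rdf_type"]], x$class_ref$iri),
                st_iri(a, pt[["has_specified_input"]], x$iri))
  }
  st <- rbind(st, process_optionals(a, rec, pt))
  named_graph(mint_graph_iri(minter, "assay-data"), "assay-data", st)
}

#' Specimen collection record
#'
#' @param process instance of the specimen collection process class.
#' @param input_material the collected material entity (exactly one).
#' @param output_specimen the specimen produced (exactly one).
#' @param agent,device,protocol,place optional instances (the device is,
#'   e.g., a live trap).
#' @param date optional ISO date.
#' @return object of class `collection_record`.
#' @export
collection_record <- function(process, input_material, output_specimen,
                              agent = NULL, device = NULL, protocol = NULL,
                              place = NULL, date = NULL) {
  stopifnot(inherits(process, "instance"),
            inherits(input_material, "instance"),
            inherits(output_specimen, "instance"))
  structure(list(process = process, input_material = input_material,
                 output_specimen = output_specimen, agent = agent,
                 device = device, protocol = protocol, place = place,
                 date = date), class = "collection_record")
}

#' Build a specimen collection named graph
#'
#' Types the process, the input material entity and the output specimen, and
#' links them as specified input/output; collection yields exactly one
#' specimen (forks belong to the specimen history).
#'
#' @param rec a [collection_record()].
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return a [named_graph()] of class `specimen-collection`.
#' @export
build_collection_graph <- function(rec, minter, pt = default_predicates()) {
  stopifnot(inherits(rec, "collection_record"))
  p <- rec$process$iri
  st <- rbind(
    st_iri(p, pt[["rdf_type"]], rec$process$class_ref$iri),
    st_iri(rec$input_material$iri, pt[["rdf_type"]],
           rec$input_material$class_ref$iri),
    st_iri(rec$output_specimen$iri, pt[["rdf_type"]],
           rec$output_specimen$class_ref$iri),
    st_iri(p, pt[["has_specified_input"]], rec$input_material$iri),
    st_iri(p, pt[["has_specified_output"]], rec$output_specimen$iri))
  st <- rbind(st, process_optionals(p, rec, pt))
  named_graph(mint_graph_iri(minter, "specimen-collection"),
              "specimen-collection", st)
}

#' A material-processing step of a specimen history
#'
#' @param process instance of the material processing class.
#' @param inputs list of input specimen instances (at least one).
#' @param outputs list of output specimen instances (at least one; two or
#'   more when the chain forks, e.g. extracting a tissue sample).
#' @return object of class `processing_step`.
#' @export
processing_step <- function(process, inputs, outputs) {
  stopifnot(inherits(process, "instance"))
  if (inherits(inputs, "instance")) inputs <- list(inputs)
  if (inherits(outputs, "instance")) outputs <- list(outputs)
  if (length(inputs) < 1L || length(outputs) < 1L) {
    akg_stop("akg_scheme_error",
             "a processing step needs at least one input and one output")
  }
  structure(list(process = process, inputs = inputs, outputs = outputs),
            class = "processing_step")
}

#' Build a specimen history named graph
#'
#' Documents the DAG of specimens derived from an initially collected
#' specimen through material-processing steps; a step with two outputs forks
#' the chain. Each specimen is typed once; steps contribute a typed process
#' plus input and output links.
#'
#' @param steps list of [processing_step()] objects forming a DAG over
#'   specimens.
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return a [named_graph()] of class `specimen-history`.
#' @export
build_history_graph <- function(steps, minter, pt = default_predicates()) {
  if (inherits(steps, "processing_step")) steps <- list(steps)
  stopifnot(length(steps) > 0L)
  edges <- do.call(rbind, lapply(steps, function(s) {
    expand.grid(from = vapply(s$inputs, `[[`, "", "iri"),
                to = vapply(s$outputs, `[[`, "", "iri"),
                stringsAsFactors = FALSE)
  }))
  if (has_cycle(edges$from, edges$to)) {
    akg_stop("akg_cycle_error", "specimen history must be acyclic")
  }
  st <- statements()
  seen <- character()
  for (s in steps) {
    st <- rbind(st, st_iri(s$process$iri, pt[["rdf_type"]],
                           s$process$class_ref$iri))
    for (x in c(s$inputs, s$outputs)) {
      if (!x$iri %in% seen) {
        seen <- c(seen, x$iri)
        st <- rbind(st, st_iri(x$iri, pt[["rdf_type"]], x$class_ref$iri))
        if (!is.na(x$label)) {
          st <- rbind(st, st_literal(x$iri, pt[["rdfs_label"]], x$label))
        }
      }
    }
    for (x in s$inputs) {
      st <- rbind(st, st_iri(s$process$iri, pt[["has_specified_input"]], x$iri))
    }
    for (x in s$outputs) {
      st <- rbind(st, st_iri(s$process$iri, pt[["has_specified_output"]], x$iri))
    }
  }
  named_graph(mint_graph_iri(minter, "specimen-history"), "specimen-history",
              st)
}

has_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  indeg <- vapply(nodes, function(n) sum(to == n), 0L)
  queue <- nodes[indeg == 0L]
  seen <- 0L
  names(indeg) <- nodes
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in to[from == v]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(nodes)
}

#' Build the assertions named graph
#'
#' Wires the document together: the results section has the instance anatomy
#' as a part; the instance anatomy has every description named graph as a
#' part; the methods section has every metadata named graph as a part. Each
#' referenced graph IRI is typed by its named-graph class, which is what the
#' union query templates filter on.
#'
#' @param results_section,methods_section section instances from
#'   [build_document_graph()].
#' @param anatomy an instance typed `instance-anatomy`.
#' @param description_graphs list of description [named_graph()]s (parthood,
#'   quality, measurement).
#' @param metadata_graphs list of metadata [named_graph()]s (assay data,
#'   specimen collection, specimen history).
#' @param assertions_iri the IRI reserved for this graph when the document
#'   graph was built.
#' @param pt predicate table.
#' @return a [named_graph()] of class `assertions`.
#' @export
build_assertions_graph <- function(results_section, methods_section, anatomy,
                                   description_graphs, metadata_graphs,
                                   assertions_iri,
                                   pt = default_predicates()) {
  stopifnot(inherits(anatomy, "instance"))
  if (is.na(anatomy$class_ref$key) ||
      anatomy$class_ref$key != "instance-anatomy") {
    akg_stop("akg_scheme_error", "anatomy must be typed instance-anatomy")
  }
  d_iris <- vapply(description_graphs, `[[`, "", "iri")
  m_iris <- vapply(metadata_graphs, `[[`, "", "iri")
  if (anyDuplicated(c(unique(d_iris), unique(m_iris)))) {
    akg_stop("akg_integrity_error",
             "a graph cannot be listed as both description and metadata")
  }
  st <- rbind(
    st_iri(results_section$iri, pt[["has_part"]], anatomy$iri),
    st_iri(anatomy$iri, pt[["rdf_type"]], anatomy$class_ref$iri))
  for (g in description_graphs) {
    st <- rbind(st,
                st_iri(anatomy$iri, pt[["has_part"]], g$iri),
                st_iri(g$iri, pt[["rdf_type"]], term(g$ng_class)$iri))
  }
  for (g in metadata_graphs) {
    st <- rbind(st,
                st_iri(methods_section$iri, pt[["has_part"]], g$iri),
                st_iri(g$iri, pt[["rdf_type"]], term(g$ng_class)$iri))
  }
  named_graph(assertions_iri, "assertions", st)
}
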