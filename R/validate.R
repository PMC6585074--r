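# Validation. Each named-graph class carries one data scheme — a declarative
# list of shape rules interpreted by a small engine — so that graphs of the
# same class are structurally comparable across descriptions. Document-level
# validation adds cross-graph referential-integrity checks.

rule <- function(id, kind, severity = "error", ...) {
  c(list(id = id, kind = kind, severity = severity), list(...))
}

violation_df <- function(graph = character(), rule = character(),
                         severity = character(), message = character()) {
  data.frame(graph = graph, rule = rule, severity = severity,
             message = message, stringsAsFactors = FALSE)
}

new_report <- function(violations) {
  violations <- violations[order(violations$graph, violations$rule,
                                 violations$message, method = "radix"), ,
                           drop = FALSE]
  rownames(violations) <- NULL
  structure(list(violations = violations,
                 passed = !any(violations$severity == "error")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s)\n",
              if (x$passed) "PASSED" else "FAILED",
              sum(x$violations$severity == "error"),
              sum(x$violations$severity == "warning")))
  if (nrow(x$violations) > 0L) print(x$violations)
  invisible(x)
}

# --- rule engine -------------------------------------------------------------

apply_rule <- function(r, g, pt, fam) {
  st <- g$statements
  ty <- st[st$p == pt[["rdf_type"]] & st$o_kind == "iri", , drop = FALSE]
  fail <- function(msg) violation_df(g$iri, r$id, r$severity, msg)
  ok <- violation_df()
  in_range <- function(n, what) {
    mx <- if (is.null(r$max)) Inf else r$max
    if (n < r$min || n > mx) {
      fail(sprintf("%s: found %d, expected %s..%s", what, n, r$min,
                   if (is.infinite(mx)) "n" else mx))
    } else ok
  }
  switch(r$kind,
    pred_count = in_range(sum(st$p == pt[[r$pred]]),
                          sprintf("statements with predicate '%s'", r$pred)),
    type_count = in_range(sum(ty$o == term(r$class)$iri),
                          sprintf("instances of '%s'", r$class)),
    type_family_count = {
      if (!nzchar(fam)) ok else {
        cat_df <- term_catalog()
        fam_iris <- cat_df$iri[cat_df$family == fam]
        in_range(sum(ty$o %in% fam_iris),
                 sprintf("type statements in quality family '%s'", fam))
      }
    },
    object_typed = {
      obs <- unique(st$o[st$p == pt[[r$pred]] & st$o_kind == "iri"])
      bad <- obs[vapply(obs, function(o) sum(ty$s == o) != 1L, logical(1))]
      if (length(bad) > 0L) {
        fail(sprintf("objects of '%s' without exactly one type: %s", r$pred,
                     paste(bad, collapse = ", ")))
      } else ok
    },
    link_subject_typed = {
      subs <- unique(st$s[st$p %in% pt[r$preds]])
      bad <- subs[vapply(subs, function(s) sum(ty$s == s) != 1L, logical(1))]
      if (length(bad) > 0L) {
        fail(sprintf("link subjects without exactly one type: %s",
                     paste(bad, collapse = ", ")))
      } else ok
    },
    typed_attached = {
      non_ty <- st[st$p != pt[["rdf_type"]], , drop = FALSE]
      attached <- union(non_ty$s, non_ty$o[non_ty$o_kind == "iri"])
      bad <- setdiff(unique(ty$s), attached)
      if (length(bad) > 0L) {
        fail(sprintf("typed nodes not attached to the graph: %s",
                     paste(bad, collapse = ", ")))
      } else ok
    },
    float_object = {
      o <- st[st$p == pt[[r$pred]], , drop = FALSE]
      v <- suppressWarnings(as.numeric(o$o))
      if (any(o$o_kind != "literal" | o$dt != XSD_FLOAT | !is.finite(v))) {
        fail(sprintf("objects of '%s' must be finite float literals", r$pred))
      } else ok
    },
    literal_datatype = {
      o <- st[st$p == pt[[r$pred]], , drop = FALSE]
      if (nrow(o) > 0L && any(o$o_kind != "literal" | o$dt != r$dt)) {
        fail(sprintf("objects of '%s' must be literals of type <%s>",
                     r$pred, r$dt))
      } else ok
    },
    no_self_loop = {
      o <- st[st$p == pt[[r$pred]], , drop = FALSE]
      if (any(o$s == o$o)) fail(sprintf("self-loop on '%s'", r$pred)) else ok
    },
    process_io_balance = {
      s_in <- unique(st$s[st$p == pt[["has_specified_input"]]])
      s_out <- unique(st$s[st$p == pt[["has_specified_output"]]])
      if (!setequal(s_in, s_out)) {
        fail("every process needs both specified inputs and outputs")
      } else ok
    },
    dag = {
      hsi <- st[st$p == pt[["has_specified_input"]], , drop = FALSE]
      hso <- st[st$p == pt[["has_specified_output"]], , drop = FALSE]
      edges <- merge(hsi[, c("s", "o")], hso[, c("s", "o")], by = "s")
      if (nrow(edges) > 0L && has_cycle(edges$o.x, edges$o.y)) {
        fail("specimen history contains a cycle")
      } else ok
    },
    typed_is_object = {
      targets <- if (!is.null(r$class)) term(r$class)$iri else {
        cat_df <- term_catalog()
        cat_df$iri[cat_df$family == r$family]
      }
      subs <- unique(ty$s[ty$o %in% targets])
      objs <- st$o[st$p == pt[[r$pred]] & st$o_kind == "iri"]
      bad <- setdiff(subs, objs)
      if (length(bad) > 0L) {
        fail(sprintf("instances not attached as '%s' objects: %s", r$pred,
                     paste(bad, collapse = ", ")))
      } else ok
    },
    specimen_connected = {
      io <- pt[c("has_specified_input", "has_specified_output")]
      procs <- unique(st$s[st$p %in% io])
      linked <- unique(st$o[st$p %in% io & st$o_kind == "iri"])
      bad <- setdiff(setdiff(unique(ty$s), procs), linked)
      if (length(bad) > 0L) {
        fail(sprintf("specimens not connected to any processing step: %s",
                     paste(bad, collapse = ", ")))
      } else ok
    },
    ng_class_refs = {
      known <- term_catalog()$iri
      bad <- setdiff(ty$o[ty$o != term("instance-anatomy")$iri], known)
      if (length(bad) > 0L) {
        fail(sprintf("referenced classes not in catalog: %s",
                     paste(bad, collapse = ", ")))
      } else ok
    },
    always_flag = fail(r$message),
    akg_stop("akg_catalog_error", "unknown rule kind '%s'", r$kind)
  )
}

# One scheme per built-in named-graph class. Schemes are data: a list of
# rules consumed by apply_rule(), so user-registered classes plug in the
# same way (see register_ng_class()).
builtin_schemes <- function() {
  io_preds <- c("has_specified_input", "has_specified_output")
  list(
    document = list(
      rule("document.doc-type", "type_count", class = "iao-document",
           min = 1, max = 1),
      rule("document.methods-present", "type_count", class = "methods-section",
           min = 1, max = 1),
      rule("document.results-present", "type_count", class = "results-section",
           min = 1, max = 1),
      rule("document.assertions-registered", "type_count",
           class = "assertions", min = 1, max = 1),
      rule("document.sections-typed", "object_typed", pred = "has_part"),
      rule("document.sections-attached", "typed_is_object",
           family = "section", pred = "has_part"),
      rule("document.assertions-typed", "object_typed",
           pred = "has_assertions_graph"),
      rule("document.attached", "typed_attached")
    ),
    parthood = list(
      rule("parthood.one-type", "pred_count", pred = "rdf_type",
           min = 1, max = 1),
      rule("parthood.one-label", "pred_count", pred = "rdfs_label",
           min = 1, max = 1),
      rule("parthood.single-edge", "pred_count", pred = "has_part",
           min = 0, max = 1),
      rule("parthood.no-self", "no_self_loop", pred = "has_part"),
      rule("parthood.attached", "typed_attached")
    ),
    quality = list(
      rule("quality.one-quality", "pred_count", pred = "has_quality",
           min = 1, max = 1),
      rule("quality.one-type", "pred_count", pred = "rdf_type",
           min = 1, max = 1),
      rule("quality.typed", "object_typed", pred = "has_quality"),
      rule("quality.family", "type_family_count", min = 1, max = 1)
    ),
    measurement = list(
      rule("measurement.one-quality", "pred_count", pred = "has_quality",
           min = 1, max = 1),
      rule("measurement.quality-typed", "object_typed", pred = "has_quality"),
      rule("measurement.one-value", "pred_count", pred = "has_value",
           min = 1, max = 1),
      rule("measurement.float-value", "float_object", pred = "has_value"),
      rule("measurement.one-unit", "pred_count", pred = "has_unit",
           min = 1, max = 1),
      rule("measurement.unit-typed", "object_typed", pred = "has_unit"),
      rule("measurement.two-types", "pred_count", pred = "rdf_type",
           min = 2, max = 2),
      rule("measurement.family", "type_family_count", min = 1, max = 1)
    ),
    `assay-data` = list(
      rule("assay.has-input", "pred_count", pred = "has_specified_input",
           min = 1),
      rule("assay.has-output", "pred_count", pred = "has_specified_output",
           min = 1),
      rule("assay.process-typed", "link_subject_typed", preds = io_preds),
      rule("assay.agent-typed", "object_typed", pred = "has_agent"),
      rule("assay.device-typed", "object_typed", pred = "has_device"),
      rule("assay.protocol-typed", "object_typed", pred = "has_protocol"),
      rule("assay.place-typed", "object_typed", pred = "has_place"),
      rule("assay.date-literal", "literal_datatype", pred = "has_date",
           dt = XSD_DATE),
      rule("assay.attached", "typed_attached")
    ),
    `specimen-collection` = list(
      rule("collection.one-input", "pred_count", pred = "has_specified_input",
           min = 1, max = 1),
      rule("collection.one-output", "pred_count",
           pred = "has_specified_output", min = 1, max = 1),
      rule("collection.input-typed", "object_typed",
           pred = "has_specified_input"),
      rule("collection.output-typed", "object_typed",
           pred = "has_specified_output"),
      rule("collection.process-typed", "link_subject_typed", preds = io_preds),
      rule("collection.agent-typed", "object_typed", pred = "has_agent"),
      rule("collection.device-typed", "object_typed", pred = "has_device"),
      rule("collection.protocol-typed", "object_typed", pred = "has_protocol"),
      rule("collection.place-typed", "object_typed", pred = "has_place"),
      rule("collection.date-literal", "literal_datatype", pred = "has_date",
           dt = XSD_DATE),
      rule("collection.attached", "typed_attached")
    ),
    `specimen-history` = list(
      rule("history.has-input", "pred_count", pred = "has_specified_input",
           min = 1),
      rule("history.has-output", "pred_count", pred = "has_specified_output",
           min = 1),
      rule("history.inputs-typed", "object_typed",
           pred = "has_specified_input"),
      rule("history.outputs-typed", "object_typed",
           pred = "has_specified_output"),
      rule("history.process-typed", "link_subject_typed", preds = io_preds),
      rule("history.io-balance", "process_io_balance"),
      rule("history.acyclic", "dag"),
      rule("history.connected", "specimen_connected"),
      rule("history.attached", "typed_attached")
    ),
    assertions = list(
      rule("assertions.one-anatomy", "type_count", class = "instance-anatomy",
           min = 1, max = 1),
      rule("assertions.parts-typed", "object_typed", pred = "has_part"),
      rule("assertions.anatomy-in-results", "typed_is_object",
           class = "instance-anatomy", pred = "has_part"),
      rule("assertions.attached", "typed_attached"),
      rule("assertions.known-classes", "ng_class_refs")
    ),
    unclassified = list(
      rule("graph.unclassified", "always_flag", severity = "warning",
           message = "graph class could not be recovered; scheme unknown")
    )
  )
}

#' Validate a named graph against its class's data scheme
#'
#' Checks the declarative shape rules registered for the graph's named-graph
#' class: required statement shapes present, nothing required missing,
#' nothing forbidden added (e.g. a parthood graph carries exactly one type,
#' one label and at most one parthood edge; a measurement graph carries the
#' five-statement shape with a finite float literal and a typed unit).
#'
#' @param g a [named_graph()].
#' @param pt predicate table.
#' @return object of class `validation_report` with fields `violations` (a
#'   data frame `graph`, `rule`, `severity`, `message`) and `passed`.
#' @export
validate_named_graph <- function(g, pt = default_predicates()) {
  stopifnot(inherits(g, "named_graph"))
  cat_df <- term_catalog()
  i <- match(g$ng_class, cat_df$key)
  if (is.na(i) || !nzchar(cat_df$scheme[i])) {
    akg_stop("akg_catalog_error", "no scheme for named-graph class '%s'",
             g$ng_class)
  }
  rules <- akg_state()$schemes[[cat_df$scheme[i]]]
  out <- lapply(rules, apply_rule, g = g, pt = pt, fam = cat_df$family[i])
  new_report(do.call(rbind, c(list(violation_df()), out)))
}

#' Validate a description document across all its named graphs
#'
#' Beyond per-graph scheme conformance, checks the wiring of the whole
#' document: every graph listed in the assertions graph resolves in the
#' store; every assay output IRI is one of the anatomy's description graphs;
#' the partonomy has a unique root and no cycles. Parts with multiple
#' parents and description graphs whose provenance no assay documents are
#' reported as warnings.
#'
#' @param store a [quad_store()].
#' @param doc IRI of the document's `iao:document` instance.
#' @param pt predicate table.
#' @return a `validation_report`.
#' @export
validate_document <- function(store, doc, pt = default_predicates()) {
  v <- violation_df()
  dg <- locate_document_graph(store, doc, pt)
  ag <- locate_assertions_graph(store, dg, pt)
  anatomy <- locate_instance_anatomy(store, ag, pt)
  methods_sec <- locate_section(store, dg, "methods-section", pt)

  desc <- attached_graphs(store, anatomy, ag, pt)
  meta <- attached_graphs(store, methods_sec, ag, pt)
  resolvable <- function(iris) {
    for (i in iris) {
      if (is.null(store$graphs[[i]])) {
        v <<- rbind(v, violation_df(ag, "doc.dangling-graph", "error",
                                    sprintf("graph %s listed in assertions but absent from store", i)))
      }
    }
    iris[vapply(iris, function(i) !is.null(store$graphs[[i]]), logical(1))]
  }
  desc_ok <- resolvable(desc)
  meta_ok <- resolvable(meta)

  for (iri in unique(c(dg, ag, desc_ok, meta_ok))) {
    rep_g <- validate_named_graph(get_graph(store, iri), pt)
    v <- rbind(v, rep_g$violations)
  }

  # assay outputs must be description graphs of this document
  for (iri in meta_ok) {
    g <- get_graph(store, iri)
    if (g$ng_class == "assay-data") {
      outs <- g$statements$o[g$statements$p == pt[["has_specified_output"]]]
      bad <- setdiff(outs, desc)
      if (length(bad) > 0L) {
        v <- rbind(v, violation_df(iri, "assay.unknown-output", "error",
                                   sprintf("assay outputs not among the document's description graphs: %s",
                                           paste(bad, collapse = ", "))))
      }
    }
  }

  # partonomy integrity and provenance coverage
  parthood_iris <- desc_ok[vapply(desc_ok, function(i) {
    get_graph(store, i)$ng_class == "parthood"
  }, logical(1))]
  if (length(parthood_iris) > 0L) {
    pu <- union_graphs(store, parthood_iris)
    part_err <- tryCatch({ p <- extract_partonomy(pu, pt); NULL },
                         akg_error = function(e) conditionMessage(e))
    if (!is.null(part_err)) {
      v <- rbind(v, violation_df(ag, "partonomy.malformed", "error", part_err))
    } else {
      multi <- names(which(table(p$edges$child) > 1L))
      if (length(multi) > 0L) {
        v <- rbind(v, violation_df(ag, "partonomy.multi-parent", "warning",
                                   sprintf("parts with multiple parents: %s",
                                           paste(multi, collapse = ", "))))
      }
    }
  }
  covered <- unlist(lapply(meta_ok, function(iri) {
    g <- get_graph(store, iri)
    if (g$ng_class == "assay-data") {
      g$statements$o[g$statements$p == pt[["has_specified_output"]]]
    } else character()
  }))
  uncovered <- setdiff(desc_ok, covered)
  if (length(uncovered) > 0L) {
    v <- rbind(v, violation_df(ag, "provenance.unreferenced-graph", "warning",
                               sprintf("description graphs not output of any assay: %s",
                                       paste(uncovered, collapse = ", "))))
  }
  new_report(v)
}

#' Locate a document section instance inside the document graph
#' @param store a [quad_store()].
#' @param document_graph IRI of the document named graph.
#' @param key section catalog key (e.g. `"methods-section"`).
#' @param pt predicate table.
#' @return the section instance's IRI.
#' @export
locate_section <- function(store, document_graph, key,
                           pt = default_predicates()) {
  st <- get_graph(store, document_graph)$statements
  hits <- st$s[st$p == pt[["rdf_type"]] & st$o_kind == "iri" &
                 st$o == term(key)$iri]
  locate_unique(store, sort(unique(hits), method = "radix"),
                sprintf("'%s' instance", key))
}
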