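# Serialization. TriG is the canonical human-facing format (one block per
# named graph, mirroring the fragmentation), N-Quads the line-oriented
# exchange format. The model admits no blank nodes and no relative IRIs,
# so the reader targets exactly that subset. Query results additionally
# export to CSV and whole documents to a nested JSON rendering.

escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_lit <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    buf <- character(0); j <- 1L
    while (j <= length(chars)) {
      if (chars[[j]] == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, chars[[j]]); j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

term_to_text <- function(st) {
  ifelse(st$o_kind == "iri", paste0("<", st$o, ">"),
         paste0("\"", escape_lit(st$o), "\"",
                ifelse(!is.na(st$lang), paste0("@", st$lang),
                       ifelse(st$dt == XSD_STRING, "",
                              paste0("^^<", st$dt, ">")))))
}

#' Serialize a quad store
#'
#' @param store a [quad_store()].
#' @param format `"trig"` (one block per named graph) or `"nquads"` (one
#'   line per quad).
#' @return a single character string; `""` for an empty store.
#' @export
write_quads <- function(store, format = c("trig", "nquads")) {
  format <- match.arg(format)
  iris <- graph_iris(store)
  if (length(iris) == 0L) return("")
  blocks <- vapply(iris, function(iri) {
    g <- store$graphs[[iri]]
    st <- g$statements
    lines <- paste0("<", st$s, "> <", st$p, "> ", term_to_text(st))
    if (format == "trig") {
      paste0("<", iri, "> {\n", paste0("    ", lines, " .", collapse = "\n"),
             "\n}\n")
    } else {
      paste0(lines, " <", iri, "> .", collapse = "\n")
    }
  }, character(1))
  if (format == "trig") paste(blocks, collapse = "\n")
  else paste0(paste(blocks, collapse = "\n"), "\n")
}

IRI_RE <- "<([^<>[:space:]]*)>"
LIT_RE <- "\"((?:[^\"\\\\]|\\\\.)*)\""

parse_object <- function(tok, lineno) {
  if (grepl(paste0("^", IRI_RE, "$"), tok)) {
    list(o = sub(paste0("^", IRI_RE, "$"), "\\1", tok), o_kind = "iri",
         dt = NA_character_, lang = NA_character_)
  } else if (grepl(paste0("^", LIT_RE, "(\\^\\^", IRI_RE,
                          "|@[A-Za-z][A-Za-z0-9-]*)?$"), tok, perl = TRUE)) {
    lex <- unescape_lit(sub(paste0("^", LIT_RE, ".*$"), "\\1", tok,
                            perl = TRUE))
    rest <- sub(paste0("^", LIT_RE), "", tok, perl = TRUE)
    if (startsWith(rest, "@")) {
      list(o = lex, o_kind = "literal", dt = RDF_LANGSTR, lang = substring(rest, 2))
    } else if (startsWith(rest, "^^")) {
      list(o = lex, o_kind = "literal",
           dt = sub(paste0("^\\^\\^", IRI_RE, "$"), "\\1", rest),
           lang = NA_character_)
    } else {
      list(o = lex, o_kind = "literal", dt = XSD_STRING, lang = NA_character_)
    }
  } else {
    akg_stop("akg_parse_error", "line %d: cannot parse object term: %s",
             lineno, tok)
  }
}

# Split a statement line "<s> <p> OBJECT [<g>] ." into its terms.
parse_statement_line <- function(line, lineno, expect_graph) {
  m <- regmatches(line, regexec(paste0(
    "^[[:space:]]*", IRI_RE, "[[:space:]]+", IRI_RE, "[[:space:]]+(.*?)",
    if (expect_graph) paste0("[[:space:]]+", IRI_RE) else "",
    "[[:space:]]*\\.[[:space:]]*$"), line, perl = TRUE))[[1]]
  if (length(m) == 0L) {
    akg_stop("akg_parse_error", "line %d: malformed statement: %s",
             lineno, line)
  }
  obj <- parse_object(m[[4]], lineno)
  c(list(s = m[[2]], p = m[[3]]), obj,
    if (expect_graph) list(graph = m[[5]]) else NULL)
}

#' Parse a TriG or N-Quads serialization into a quad store
#'
#' Reads the blank-node-free subset this package writes: absolute IRIs,
#' plain/typed/language-tagged literals, one graph block (TriG) or trailing
#' graph IRI (N-Quads) per statement. Named-graph classes are recovered from
#' the type triples in the document and assertions graphs; a graph whose
#' class cannot be recovered is typed `unclassified` and flagged by the
#' validator.
#'
#' @param text serialization as a single string or character vector of lines.
#' @param format `"trig"` or `"nquads"`.
#' @return a [quad_store()].
#' @export
read_quads <- function(text, format = c("trig", "nquads")) {
  format <- match.arg(format)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rows <- list()
  if (format == "nquads") {
    for (i in seq_along(lines)) {
      line <- lines[[i]]
      if (!nzchar(trimws(line)) || grepl("^[[:space:]]*#", line)) next
      rows[[length(rows) + 1L]] <- parse_statement_line(line, i, TRUE)
    }
  } else {
    current <- NULL
    for (i in seq_along(lines)) {
      line <- lines[[i]]
      if (!nzchar(trimws(line)) || grepl("^[[:space:]]*#", line)) next
      open <- regmatches(line, regexec(
        paste0("^[[:space:]]*", IRI_RE, "[[:space:]]*\\{[[:space:]]*$"), line))[[1]]
      if (length(open) > 0L) {
        if (!is.null(current)) {
          akg_stop("akg_parse_error", "line %d: nested graph block", i)
        }
        current <- open[[2]]
      } else if (grepl("^[[:space:]]*\\}[[:space:]]*$", line)) {
        if (is.null(current)) {
          akg_stop("akg_parse_error", "line %d: '}' outside a graph block", i)
        }
        current <- NULL
      } else {
        if (is.null(current)) {
          akg_stop("akg_parse_error", "line %d: statement outside a graph block", i)
        }
        row <- parse_statement_line(line, i, FALSE)
        row$graph <- current
        rows[[length(rows) + 1L]] <- row
      }
    }
    if (!is.null(current)) {
      akg_stop("akg_parse_error", "unterminated graph block: <%s>", current)
    }
  }
  quads_to_store(rows)
}

quads_to_store <- function(rows) {
  store <- quad_store()
  if (length(rows) == 0L) return(store)
  q <- do.call(rbind, lapply(rows, function(r) {
    data.frame(s = r$s, p = r$p, o = r$o, o_kind = r$o_kind, dt = r$dt,
               lang = r$lang, graph = r$graph, stringsAsFactors = FALSE)
  }))
  assert_iri(unique(c(q$s, q$p, q$graph)), "term in quad file")
  pt <- default_predicates()
  ng_iris <- unique(q$graph)
  # class recovery: a graph holding the iao:document typing is the document
  # graph; all other graphs are typed by statements elsewhere in the store
  doc_class <- term("iao-document")$iri
  type_rows <- q[q$p == pt[["rdf_type"]] & q$o_kind == "iri", , drop = FALSE]
  for (iri in sort(ng_iris, method = "radix")) {
    st <- q[q$graph == iri, st_cols, drop = FALSE]
    is_doc <- any(type_rows$graph == iri & type_rows$o == doc_class)
    cls_iris <- type_rows$o[type_rows$s == iri]
    key <- if (is_doc) "document" else {
      keys <- stats::na.omit(vapply(cls_iris, ng_class_key_for_iri,
                                    character(1)))
      if (length(keys) > 0L) keys[[1L]] else "unclassified"
    }
    add_graph(store, named_graph(iri, key, st))
  }
  store
}

#' Export statements as tabular rows
#'
#' @param st statement data frame (e.g. a view resolution or union output).
#' @return data frame with columns `s`, `p`, `o`, `o_datatype` (empty for
#'   IRI objects; the language-string datatype for tagged literals), one row
#'   per statement in deterministic order.
#' @export
export_csv <- function(st) {
  st <- st_union(st)
  data.frame(s = st$s, p = st$p, o = st$o,
             o_datatype = ifelse(st$o_kind == "iri", "", st$dt),
             stringsAsFactors = FALSE)
}

#' Write statements to an RFC 4180 CSV file
#' @param st statement data frame.
#' @param file path or connection.
#' @return the exported data frame, invisibly.
#' @export
write_statements_csv <- function(st, file) {
  out <- export_csv(st)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Export a description document as nested JSON
#'
#' Renders the document graph, its sections, the instance anatomy and every
#' named graph (with class key, role and statements) as a stable-keyed JSON
#' string suitable for service requests.
#'
#' @param store a [quad_store()].
#' @param doc IRI of the `iao:document` instance.
#' @param pt predicate table.
#' @return a JSON string (class `json`).
#' @export
export_document_json <- function(store, doc, pt = default_predicates()) {
  dg <- locate_document_graph(store, doc, pt)
  ag <- locate_assertions_graph(store, dg, pt)
  anatomy <- locate_instance_anatomy(store, ag, pt)
  methods_sec <- locate_section(store, dg, "methods-section", pt)
  dst <- get_graph(store, dg)$statements
  title <- dst$o[dst$p == pt[["has_title"]]]
  section_of <- function(key) {
    iri <- tryCatch(locate_section(store, dg, key, pt),
                    akg_error = function(e) NULL)
    if (is.null(iri)) return(NULL)
    text <- dst$o[dst$s == iri & dst$p == pt[["has_free_text"]]]
    list(iri = iri, class = key,
         text = if (length(text) > 0L) text[[1L]] else "")
  }
  sections <- Filter(Negate(is.null),
                     stats::setNames(lapply(SECTION_KEYS, section_of),
                                     SECTION_KEYS))
  desc <- attached_graphs(store, anatomy, ag, pt)
  meta <- attached_graphs(store, methods_sec, ag, pt)
  graph_obj <- function(iri, role) {
    g <- get_graph(store, iri)
    st <- g$statements
    st$dt[is.na(st$dt)] <- ""
    st$lang[is.na(st$lang)] <- ""
    list(iri = iri, ng_class = g$ng_class, role = role, statements = st)
  }
  all_iris <- sort(c(desc, meta), method = "radix")
  roles <- ifelse(all_iris %in% desc, "description", "metadata")
  report <- validate_document(store, doc, pt)
  out <- list(
    document = doc,
    title = if (length(title) > 0L) title[[1L]] else "",
    document_graph = dg,
    assertions_graph = ag,
    instance_anatomy = anatomy,
    valid = report$passed,
    sections = sections,
    graphs = mapply(graph_obj, all_iris, roles, SIMPLIFY = FALSE,
                    USE.NAMES = FALSE)
  )
  jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                   dataframe = "rows")
}
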