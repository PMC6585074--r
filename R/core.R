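#' @keywords internal
"_PACKAGE"

# Classed conditions used throughout: every user-facing error carries a
# subclass of "akg_error" so callers and tests can discriminate failure modes.
akg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "akg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Check that a string is an absolute IRI
#'
#' The data model bans blank nodes: every subject, predicate and every
#' instance must carry its own absolute IRI. An IRI here must be non-empty,
#' contain a scheme (`scheme:`), and contain no whitespace or angle brackets.
#'
#' @param x character vector to check.
#' @return `TRUE` for each valid IRI, `FALSE` otherwise.
#' @export
is_iri <- function(x) {
  is.character(x) & !is.na(x) & nzchar(x) &
    grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) &
    !grepl("[[:space:]<>\"{}|\\\\^`]", x)
}

assert_iri <- function(x, what = "IRI") {
  bad <- !is_iri(x)
  if (any(bad)) {
    akg_stop("akg_iri_error", "invalid %s: %s", what,
             paste(utils::head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}

## Well-known vocabulary -----------------------------------------------------

RDF_TYPE    <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL  <- "http://www.w3.org/2000/01/rdf-schema#label"
XSD         <- "http://www.w3.org/2001/XMLSchema#"
XSD_STRING  <- paste0(XSD, "string")
XSD_FLOAT   <- paste0(XSD, "float")
XSD_DATE    <- paste0(XSD, "date")
RDF_LANGSTR <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#langString"
OBO         <- "http://purl.obolibrary.org/obo/"

# Namespace under which this package's own named-graph classes and helper
# classes are minted: the source model names classes ('parthood named graph',
# 'instance anatomy', ...) without publishing IRIs, so we assign stable,
# citable ones in a project namespace.
AKG_NS    <- "https://w3id.org/anatomygraphs/"
AKG_NGO   <- paste0(AKG_NS, "ngo/")
AKG_CLASS <- paste0(AKG_NS, "class/")
AKG_PROP  <- paste0(AKG_NS, "prop/")

#' Default predicate table
#'
#' The parthood predicate is fixed to BFO 0000051 (`has part`); quality,
#' measurement and provenance predicates default to OBO / RO / IAO / OBI
#' property IRIs where an established one exists and to the package property
#' namespace otherwise. Builders take the table as an argument, so a
#' deployment can swap any entry.
#'
#' @return named character vector of absolute predicate IRIs.
#' @export
#' @examples
#' default_predicates()[["has_part"]]
default_predicates <- function() {
  c(
    rdf_type             = RDF_TYPE,
    rdfs_label           = RDFS_LABEL,
    has_part             = paste0(OBO, "BFO_0000051"),
    has_quality          = paste0(OBO, "RO_0000086"),
    has_value            = paste0(OBO, "IAO_0000004"),
    has_unit             = paste0(OBO, "IAO_0000039"),
    has_specified_input  = paste0(OBO, "OBI_0000293"),
    has_specified_output = paste0(OBO, "OBI_0000299"),
    has_agent            = "http://www.w3.org/ns/prov#wasAssociatedWith",
    has_device           = paste0(AKG_PROP, "has_device"),
    has_protocol         = paste0(AKG_PROP, "follows_protocol"),
    has_place            = "http://www.w3.org/ns/prov#atLocation",
    has_date             = "http://purl.org/dc/terms/date",
    has_free_text        = paste0(AKG_PROP, "has_free_text"),
    has_title            = "http://purl.org/dc/terms/title",
    has_assertions_graph = paste0(AKG_PROP, "has_assertions_graph")
  )
}

## Statements ----------------------------------------------------------------

# A statement set is a data.frame with columns
#   s, p      : absolute IRIs
#   o         : object IRI or literal lexical form
#   o_kind    : "iri" | "literal"
#   dt        : datatype IRI (NA for IRI objects)
#   lang      : language tag (NA unless a language-tagged string)
# Set semantics: helpers canonicalize (sort + deduplicate) on construction.

st_cols <- c("s", "p", "o", "o_kind", "dt", "lang")

#' Create an empty statement set
#' @return zero-row statement data frame.
#' @export
statements <- function() {
  data.frame(s = character(), p = character(), o = character(),
             o_kind = character(), dt = character(), lang = character(),
             stringsAsFactors = FALSE)
}

#' Build statements with IRI objects
#' @param s,p,o subject, predicate and object IRIs (recycled).
#' @return statement data frame, one row per triple.
#' @export
st_iri <- function(s, p, o) {
  assert_iri(s, "subject"); assert_iri(p, "predicate"); assert_iri(o, "object")
  data.frame(s = s, p = p, o = o, o_kind = "iri",
             dt = NA_character_, lang = NA_character_,
             stringsAsFactors = FALSE)
}

#' Build statements with literal objects
#' @param s,p subject and predicate IRIs.
#' @param lexical lexical form of the literal.
#' @param dt datatype IRI; defaults to `xsd:string`.
#' @param lang optional language tag; forces the language-string datatype.
#' @return statement data frame, one row per triple.
#' @export
st_literal <- function(s, p, lexical, dt = XSD_STRING, lang = NA_character_) {
  assert_iri(s, "subject"); assert_iri(p, "predicate")
  if (any(!is.na(lang))) dt <- ifelse(is.na(lang), dt, RDF_LANGSTR)
  if (any(dt == XSD_FLOAT)) {
    v <- suppressWarnings(as.numeric(lexical[dt == XSD_FLOAT]))
    if (any(is.na(v) | !is.finite(v))) {
      akg_stop("akg_value_error", "float literal must be a finite number")
    }
  }
  data.frame(s = s, p = p, o = as.character(lexical), o_kind = "literal",
             dt = dt, lang = lang, stringsAsFactors = FALSE)
}

st_key <- function(st) {
  paste(st$s, st$p, st$o, st$o_kind,
        ifelse(is.na(st$dt), "", st$dt),
        ifelse(is.na(st$lang), "", st$lang), sep = "\r")
}

#' Combine statement sets with set semantics
#' @param ... statement data frames.
#' @return canonical (sorted, deduplicated) statement data frame.
#' @export
st_union <- function(...) {
  st <- do.call(rbind, Filter(Negate(is.null), list(...)))
  if (is.null(st) || nrow(st) == 0L) return(statements())
  st <- st[!duplicated(st_key(st)), , drop = FALSE]
  st <- st[order(st$s, st$p, st$o_kind, st$o, st$dt, st$lang,
                 method = "radix"), , drop = FALSE]
  rownames(st) <- NULL
  st
}

#' Test two statement sets for set equality
#' @param a,b statement data frames.
#' @return `TRUE` if they contain exactly the same statements.
#' @export
st_equal <- function(a, b) {
  setequal(st_key(a), st_key(b))
}

## IRI minting ---------------------------------------------------------------

#' Create a deterministic IRI minter
#'
#' Every part, quality instance and named graph possesses its own IRI. The
#' minter derives fresh IRIs as `base + kind + "/" + tag + "-" + counter`,
#' where the tag is a hex fingerprint of the seed: identical seed and call
#' sequence give identical IRIs, and the per-kind counter makes collisions
#' within a store impossible.
#'
#' @param base IRI prefix under which to mint (must be a valid IRI).
#' @param seed integer seed controlling the run tag.
#' @return an object of class `iri_minter`.
#' @export
#' @examples
#' m <- iri_minter("https://example.org/", seed = 42)
#' mint_iri(m, "instance")
iri_minter <- function(base = "https://example.org/akg/", seed = 1L) {
  assert_iri(base, "minter base")
  if (!grepl("[/#]$", base)) base <- paste0(base, "/")
  e <- new.env(parent = emptyenv())
  e$base <- base
  e$tag <- sprintf("%08x", as.integer((as.numeric(seed) * 2654435761) %% 2147483647))
  e$counters <- new.env(parent = emptyenv())
  structure(e, class = "iri_minter")
}

#' Mint a fresh IRI
#' @param minter an [iri_minter()].
#' @param kind short slug naming what is minted (catalog key or `"instance"`).
#' @return a fresh absolute IRI, never repeated by this minter.
#' @export
mint_iri <- function(minter, kind = "instance") {
  stopifnot(inherits(minter, "iri_minter"))
  kind <- gsub("[^A-Za-z0-9_-]", "-", kind)
  n <- (get0(kind, envir = minter$counters, ifnotfound = 0L)) + 1L
  assign(kind, n, envir = minter$counters)
  paste0(minter$base, kind, "/", minter$tag, "-", n)
}

#' @export
print.iri_minter <- function(x, ...) {
  cat("<iri_minter> base:", x$base, " tag:", x$tag, "\n")
  invisible(x)
}
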