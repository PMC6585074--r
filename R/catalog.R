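# Term catalog: the bundled offline snapshot of every ontology class the
# builders use (IAO document parts, OBI processes, PATO qualities, UO units,
# HAO/UBERON anatomy) plus the named-graph classes this model introduces.
# The catalog is data, not code: new classes, qualities and named-graph
# schemes are registered at run time.

.akg <- new.env(parent = emptyenv())

akg_state <- function() {
  if (is.null(.akg$catalog)) reset_catalog()
  .akg
}

#' Reset the term catalog and registries to the bundled defaults
#'
#' Reloads the shipped term catalog, the built-in named-graph validation
#' schemes and the built-in data views, discarding any run-time
#' registrations.
#'
#' @return the catalog data frame, invisibly.
#' @export
reset_catalog <- function() {
  path <- system.file("extdata", "term_catalog.tsv", package = "anatomygraphs")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "term_catalog.tsv")
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                              na.strings = c("NA", ""))
  cat_df$family[is.na(cat_df$family)] <- ""
  cat_df$scheme[is.na(cat_df$scheme)] <- ""
  if (anyDuplicated(cat_df$key)) {
    akg_stop("akg_catalog_error", "duplicate keys in term catalog")
  }
  .akg$catalog <- cat_df
  .akg$prefixes <- unique(cat_df$prefix)
  .akg$schemes <- builtin_schemes()
  .akg$views <- new.env(parent = emptyenv())
  for (v in builtin_views()) assign(v$name, v, envir = .akg$views)
  invisible(cat_df)
}

#' The current term catalog
#' @return data frame with columns `key`, `prefix`, `iri`, `label`,
#'   `ontology`, `family`, `scheme`.
#' @export
term_catalog <- function() akg_state()$catalog

#' Look up a catalog term
#'
#' @param key catalog key (e.g. `"head"`, `"milliliter"`, `"parthood"`).
#' @return a `term_ref`: list with `iri`, `label`, `prefix`, `key`.
#' @export
#' @examples
#' term("milliliter")$label
term <- function(key) {
  cat_df <- term_catalog()
  i <- match(key, cat_df$key)
  if (is.na(i)) {
    akg_stop("akg_catalog_error", "term key not in catalog: '%s'", key)
  }
  term_ref(cat_df$iri[i], cat_df$label[i], cat_df$prefix[i], key = key)
}

#' Construct a term reference
#' @param iri absolute class IRI.
#' @param label short human-readable label (required).
#' @param prefix ontology short name; must be a catalog prefix or a
#'   registered namespace.
#' @param key optional catalog key.
#' @return object of class `term_ref`.
#' @export
term_ref <- function(iri, label, prefix, key = NA_character_) {
  assert_iri(iri, "term IRI")
  if (!nzchar(label)) akg_stop("akg_catalog_error", "term label must be non-empty")
  if (!prefix %in% akg_state()$prefixes) {
    akg_stop("akg_catalog_error",
             "unknown ontology prefix '%s'; register it first", prefix)
  }
  structure(list(iri = iri, label = label, prefix = prefix, key = key),
            class = "term_ref")
}

#' Register an ontology namespace prefix
#' @param prefix short name to allow in [term_ref()].
#' @return invisibly, the updated prefix set.
#' @export
register_namespace <- function(prefix) {
  st <- akg_state()
  st$prefixes <- union(st$prefixes, prefix)
  invisible(st$prefixes)
}

#' Register a term in the catalog
#'
#' @param key unique catalog key.
#' @param iri absolute class IRI.
#' @param label human-readable label.
#' @param prefix ontology short name (registered if new).
#' @param ontology source ontology note.
#' @param family optional family tag (`"texture"`, `"part"`,
#'   `"metre-unit"`, ...) used by quality checks and unit filters.
#' @return the new `term_ref`, invisibly.
#' @export
register_term <- function(key, iri, label, prefix, ontology = "local",
                          family = "") {
  st <- akg_state()
  if (key %in% st$catalog$key) {
    akg_stop("akg_catalog_error", "catalog key already registered: '%s'", key)
  }
  assert_iri(iri, "term IRI")
  register_namespace(prefix)
  st$catalog <- rbind(st$catalog, data.frame(
    key = key, prefix = prefix, iri = iri, label = label,
    ontology = ontology, family = family, scheme = "",
    stringsAsFactors = FALSE))
  invisible(term(key))
}

#' Register a named-graph class with its validation scheme
#'
#' Each named-graph class carries exactly one data scheme; registering the
#' class and its scheme together keeps that one-to-one mapping intact, which
#' is what makes graphs of the same class comparable across descriptions.
#'
#' @param key catalog key for the new class.
#' @param label human-readable label; the class IRI is minted in the package
#'   named-graph-class namespace unless `iri` is given.
#' @param scheme a list of shape rules (see [validate_named_graph()]), or the
#'   name of an already-registered scheme to share.
#' @param iri optional explicit class IRI.
#' @param family optional family tag (e.g. a PATO quality family for a new
#'   quality category).
#' @return the new `term_ref`, invisibly.
#' @export
register_ng_class <- function(key, label, scheme, iri = NULL, family = "") {
  st <- akg_state()
  if (is.null(iri)) iri <- paste0(AKG_NGO, key, "-named-graph")
  if (is.character(scheme)) {
    if (is.null(st$schemes[[scheme]])) {
      akg_stop("akg_catalog_error", "no such scheme: '%s'", scheme)
    }
    scheme_id <- scheme
  } else {
    scheme_id <- key
    st$schemes[[key]] <- scheme
  }
  register_term(key, iri, label, prefix = "ngo", ontology = "local",
                family = family)
  st$catalog$scheme[st$catalog$key == key] <- scheme_id
  invisible(term(key))
}

#' Keys of all registered named-graph classes
#' @return character vector of catalog keys that denote named-graph classes.
#' @export
ng_class_keys <- function() {
  cat_df <- term_catalog()
  cat_df$key[nzchar(cat_df$scheme)]
}

ng_class_key_for_iri <- function(iri) {
  cat_df <- term_catalog()
  i <- which(cat_df$iri == iri & nzchar(cat_df$scheme))
  if (length(i) == 0L) NA_character_ else cat_df$key[i[1L]]
}

#' Create an ontology individual
#'
#' Every instance instantiates exactly one catalog class at creation and
#' receives its own freshly minted IRI; there are no anonymous individuals
#' anywhere in the model.
#'
#' @param class_ref a `term_ref` or a catalog key.
#' @param label optional human-readable label.
#' @param minter an [iri_minter()].
#' @return object of class `instance` with fields `iri`, `class_ref`,
#'   `label`.
#' @export
#' @examples
#' m <- iri_minter(seed = 1)
#' head_inst <- make_instance("head", "head of specimen A", m)
make_instance <- function(class_ref, label = NULL, minter) {
  if (is.character(class_ref)) class_ref <- term(class_ref)
  stopifnot(inherits(class_ref, "term_ref"))
  if (!class_ref$prefix %in% akg_state()$prefixes) {
    akg_stop("akg_catalog_error", "unknown ontology prefix '%s'",
             class_ref$prefix)
  }
  kind <- if (!is.na(class_ref$key)) class_ref$key else "instance"
  structure(list(iri = mint_iri(minter, kind), class_ref = class_ref,
                 label = if (is.null(label)) NA_character_ else label),
            class = "instance")
}

#' @export
print.instance <- function(x, ...) {
  cat(sprintf("<instance> %s\n  a %s (%s)\n", x$iri, x$class_ref$label,
              x$class_ref$iri))
  if (!is.na(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' @export
print.term_ref <- function(x, ...) {
  cat(sprintf("<term> %s:%s <%s>\n", x$prefix, x$label, x$iri))
  invisible(x)
}
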