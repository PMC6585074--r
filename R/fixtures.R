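# Synthetic description generator. Emulates a complete description document:
# a random partonomy, texture and measurement annotations sampled per part,
# a collection record, a specimen history with forks, and assays that
# partition the description graphs among the specimens. Fully reproducible
# from one seed, with a ground-truth record for recovery tests. Also home of
# the fixed worked example (a hymenopteran with a head volume in milliliter
# and a thorax surface texture).

#' Wire a complete description document into a quad store
#'
#' Shared composer behind [generate_description()], [worked_example()] and the
#' command-line `build` command: builds one named graph per descriptive or
#' metadata statement and the document and assertions graphs that tie them
#' together.
#'
#' @param meta a [document_metadata()].
#' @param root root part instance (labeled).
#' @param edges list of `list(parent = , child = )` part instances, parents
#'   before children.
#' @param qualities list of [quality_record()]s.
#' @param measurements list of [measurement_record()]s.
#' @param collection a [collection_record()] or `NULL`.
#' @param steps list of [processing_step()]s or `NULL`.
#' @param assay_specs list of `list(assay = , specimen = , graphs = )` where
#'   `graphs` are integer indices into the description-graph list (parthood
#'   graphs first, then quality, then measurement graphs).
#' @param minter an [iri_minter()].
#' @param pt predicate table.
#' @return list with `store`, `doc` (document instance IRI),
#'   `document_graph`, `assertions_graph`, `anatomy`, `sections`,
#'   `description_graphs`, `metadata_graphs`.
#' @export
compose_document <- function(meta, root, edges = list(), qualities = list(),
                             measurements = list(), collection = NULL,
                             steps = NULL, assay_specs = list(), minter,
                             pt = default_predicates()) {
  desc <- list(build_root_parthood_graph(root, minter, pt))
  for (e in edges) {
    desc <- c(desc, list(build_parthood_graph(e$parent, e$child, minter, pt)))
  }
  for (q in qualities) {
    desc <- c(desc, list(build_quality_graph(q, minter, pt)))
  }
  for (m in measurements) {
    desc <- c(desc, list(build_measurement_graph(m, minter, pt)))
  }
  meta_graphs <- list()
  if (!is.null(collection)) {
    meta_graphs <- c(meta_graphs,
                     list(build_collection_graph(collection, minter, pt)))
  }
  if (!is.null(steps) && length(steps) > 0L) {
    meta_graphs <- c(meta_graphs, list(build_history_graph(steps, minter, pt)))
  }
  desc_iris <- vapply(desc, `[[`, "", "iri")
  for (a in assay_specs) {
    rec <- assay_record(a$assay, a$specimen, desc_iris[a$graphs],
                        agent = a$agent, device = a$device,
                        protocol = a$protocol, place = a$place, date = a$date)
    meta_graphs <- c(meta_graphs, list(build_assay_graph(rec, minter, pt)))
  }
  doc <- make_instance("iao-document", if (nzchar(meta$title)) meta$title, minter)
  assertions_iri <- mint_graph_iri(minter, "assertions")
  dg <- build_document_graph(meta, doc, assertions_iri, minter, pt)
  sections <- attr(dg, "sections")
  anatomy <- make_instance("instance-anatomy", NULL, minter)
  ag <- build_assertions_graph(sections[["results-section"]],
                               sections[["methods-section"]], anatomy,
                               desc, meta_graphs, assertions_iri, pt)
  store <- quad_store()
  for (g in c(list(dg, ag), desc, meta_graphs)) add_graph(store, g)
  list(store = store, doc = doc$iri, document_graph = dg$iri,
       assertions_graph = ag$iri, anatomy = anatomy$iri,
       sections = lapply(sections, `[[`, "iri"),
       description_graphs = desc, metadata_graphs = meta_graphs)
}

#' Configuration for the synthetic-description generator
#'
#' @param seed integer seed driving structure and values through one RNG
#'   stream.
#' @param n_parts number of parts including the root (>= 1).
#' @param max_depth maximum partonomy depth (root = depth 1).
#' @param p_texture,p_measurement per-part probabilities of a surface-texture
#'   annotation / a measurement.
#' @param n_specimens total number of specimens in the history (>= 2: the
#'   collected specimen plus derived ones).
#' @param p_fork probability that a processing step yields two outputs.
#' @param unit_mix named numeric vector `c(volume = , length = )` mixing the
#'   measurement kinds.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_parts = 8L, max_depth = 4L,
                           p_texture = 0.3, p_measurement = 0.4,
                           n_specimens = 3L, p_fork = 0.25,
                           unit_mix = c(volume = 0.5, length = 0.5)) {
  probs <- c(p_texture, p_measurement, p_fork)
  if (any(probs < 0 | probs > 1)) {
    akg_stop("akg_config_error", "probabilities must lie in [0, 1]")
  }
  if (n_parts < 1L) akg_stop("akg_config_error", "n_parts must be >= 1")
  if (max_depth < 1L) akg_stop("akg_config_error", "max_depth must be >= 1")
  if (n_specimens < 2L) akg_stop("akg_config_error", "n_specimens must be >= 2")
  structure(list(seed = as.integer(seed), n_parts = as.integer(n_parts),
                 max_depth = as.integer(max_depth), p_texture = p_texture,
                 p_measurement = p_measurement,
                 n_specimens = as.integer(n_specimens), p_fork = p_fork,
                 unit_mix = unit_mix / sum(unit_mix)),
            class = "fixture_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a complete synthetic description document
#'
#' Builds a validating description document from a random partonomy tree
#' (uniform attachment up to the configured depth), texture and measurement
#' annotations sampled per part, a collection record, a specimen history
#' with forks, and assays that partition the description graphs among the
#' specimens. Identical seeds give identical stores.
#'
#' @param cfg a [fixture_config()].
#' @param base base IRI for minting.
#' @param pt predicate table.
#' @return list as for [compose_document()], plus `ground_truth`: a list with
#'   the generating tree (`parent_of`, named by child IRI), part `labels` and
#'   `classes`, the sampled `qualities` and `measurements` (with values and
#'   units), the specimen-history `specimens` and `step_edges`, and
#'   `graph_specimen` mapping each description graph IRI to the specimen
#'   whose assay produced it.
#' @export
generate_description <- function(cfg = fixture_config(),
                                 base = "https://example.org/akg/",
                                 pt = default_predicates()) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed, {
    minter <- iri_minter(base, cfg$seed)
    cat_df <- term_catalog()
    part_keys <- cat_df$key[cat_df$family == "part"]
    texture_keys <- setdiff(cat_df$key[cat_df$family == "texture"], "texture")

    root <- make_instance("organism", "whole organism of described specimen",
                          minter)
    parts <- list(root)
    depth <- c(1L)
    edges <- list()
    if (cfg$n_parts > 1L) {
      for (i in 2:cfg$n_parts) {
        eligible <- which(depth < cfg$max_depth)
        pa <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        key <- sample(part_keys, 1L)
        child <- make_instance(key, sprintf("%s (part %d)", term(key)$label, i),
                               minter)
        parts <- c(parts, list(child))
        depth <- c(depth, depth[[pa]] + 1L)
        edges <- c(edges, list(list(parent = parts[[pa]], child = child)))
      }
    }

    qualities <- list()
    measurements <- list()
    for (p in parts) {
      if (stats::runif(1) < cfg$p_texture) {
        qualities <- c(qualities, list(quality_record(
          p, sample(texture_keys, 1L), "anatomical-surface-texture")))
      }
      if (stats::runif(1) < cfg$p_measurement) {
        if (stats::runif(1) < cfg$unit_mix[["volume"]]) {
          measurements <- c(measurements, list(measurement_record(
            p, "volume", 10^stats::runif(1, -2, 1), "milliliter",
            "anatomical-structure-volume")))
        } else {
          unit <- sample(c("meter", "centimeter", "millimeter", "micrometer"), 1L)
          measurements <- c(measurements, list(measurement_record(
            p, "length", 10^stats::runif(1, -1, 2), unit,
            "anatomical-structure-length")))
        }
      }
    }

    material <- make_instance("material-entity", "field-collected material",
                              minter)
    specimen_a <- make_instance("specimen", "specimen A", minter)
    collection <- collection_record(
      make_instance("specimen-collection-process", NULL, minter),
      material, specimen_a,
      agent = make_instance("person", "collector", minter),
      device = make_instance("live-trap", "live trap", minter),
      date = "2019-05-04")

    specimens <- list(specimen_a)
    steps <- list()
    step_edges <- data.frame(from = character(), to = character(),
                             stringsAsFactors = FALSE)
    while (length(specimens) < cfg$n_specimens) {
      src <- specimens[[sample(length(specimens), 1L)]]
      n_out <- if (stats::runif(1) < cfg$p_fork &&
                   length(specimens) + 2L <= cfg$n_specimens) 2L else 1L
      outs <- lapply(seq_len(n_out), function(k) {
        make_instance("specimen",
                      sprintf("specimen %d", length(specimens) + k), minter)
      })
      steps <- c(steps, list(processing_step(
        make_instance("material-processing", NULL, minter), list(src), outs)))
      step_edges <- rbind(step_edges, data.frame(
        from = src$iri, to = vapply(outs, `[[`, "", "iri"),
        stringsAsFactors = FALSE))
      specimens <- c(specimens, outs)
    }

    n_desc <- 1L + length(edges) + length(qualities) + length(measurements)
    assign_to <- sample(length(specimens), n_desc, replace = TRUE)
    assay_specs <- lapply(sort(unique(assign_to)), function(si) {
      list(assay = make_instance("microscopy-assay", NULL, minter),
           specimen = specimens[[si]], graphs = which(assign_to == si),
           agent = make_instance("person", "observer", minter),
           device = make_instance("device", "light microscope", minter),
           date = "2020-02-11")
    })

    meta <- document_metadata(
      title = sprintf("Synthetic description (seed %d)", cfg$seed),
      sections = stats::setNames(
        c("Generated morphological description.", rep("", 7)),
        c("abstract", setdiff(SECTION_KEYS, "abstract"))))

    out <- compose_document(meta, root, edges, qualities, measurements,
                            collection, steps, assay_specs, minter, pt)
    desc_iris <- vapply(out$description_graphs, `[[`, "", "iri")
    graph_specimen <- character(n_desc)
    for (a in assay_specs) graph_specimen[a$graphs] <- a$specimen$iri
    out$ground_truth <- list(
      root = root$iri,
      parent_of = stats::setNames(
        vapply(edges, function(e) e$parent$iri, ""),
        vapply(edges, function(e) e$child$iri, "")),
      labels = stats::setNames(
        vapply(parts, `[[`, "", "label"),
        vapply(parts, `[[`, "", "iri")),
      classes = stats::setNames(
        vapply(parts, function(p) p$class_ref$iri, ""),
        vapply(parts, `[[`, "", "iri")),
      qualities = qualities, measurements = measurements,
      specimens = vapply(specimens, `[[`, "", "iri"),
      step_edges = step_edges,
      graph_specimen = stats::setNames(graph_specimen, desc_iris))
    out
  })
}

#' Rebuild a description as one monolithic statement set
#'
#' Constructs, directly from a generator ground-truth record and without
#' going through the named-graph builders or the union machinery, the
#' statement set of the same description as a single unfragmented graph.
#' Comparing it with [description_union()] checks the central losslessness
#' property: fragmenting a description into named graphs loses no
#' information.
#'
#' @param fx output of [generate_description()].
#' @param pt predicate table.
#' @return statement data frame.
#' @export
build_monolithic_description <- function(fx, pt = default_predicates()) {
  gt <- fx$ground_truth
  st <- statements()
  for (iri in names(gt$labels)) {
    st <- rbind(st,
                st_iri(iri, pt[["rdf_type"]], gt$classes[[iri]]),
                st_literal(iri, pt[["rdfs_label"]], gt$labels[[iri]]))
  }
  for (child in names(gt$parent_of)) {
    st <- rbind(st, st_iri(gt$parent_of[[child]], pt[["has_part"]], child))
  }
  # quality and measurement instance IRIs are read back from the fixture's
  # graphs (they were minted during the build); the statement structure is
  # reconstructed here independently
  desc <- fx$description_graphs
  for (g in desc) {
    cls_family <- term_catalog()$scheme[match(g$ng_class, term_catalog()$key)]
    if (cls_family == "quality") {
      gs <- g$statements
      q <- gs$o[gs$p == pt[["has_quality"]]]
      bearer <- gs$s[gs$p == pt[["has_quality"]]]
      qcls <- gs$o[gs$p == pt[["rdf_type"]] & gs$s == q]
      st <- rbind(st,
                  st_iri(bearer, pt[["has_quality"]], q),
                  st_iri(q, pt[["rdf_type"]], qcls))
    } else if (cls_family == "measurement") {
      gs <- g$statements
      q <- gs$o[gs$p == pt[["has_quality"]]]
      bearer <- gs$s[gs$p == pt[["has_quality"]]]
      qcls <- gs$o[gs$p == pt[["rdf_type"]] & gs$s == q]
      u <- gs$o[gs$p == pt[["has_unit"]]]
      ucls <- gs$o[gs$p == pt[["rdf_type"]] & gs$s == u]
      val <- gs$o[gs$p == pt[["has_value"]]]
      st <- rbind(st,
                  st_iri(bearer, pt[["has_quality"]], q),
                  st_iri(q, pt[["rdf_type"]], qcls),
                  st_literal(q, pt[["has_value"]], val, dt = XSD_FLOAT),
                  st_iri(q, pt[["has_unit"]], u),
                  st_iri(u, pt[["rdf_type"]], ucls))
    }
  }
  st_union(st)
}

#' The fixed worked example
#'
#' A small hymenopteran description exercising every named-graph class once:
#' a two-level partonomy (whole organism with head and thorax), a rough
#' surface texture on the thorax, a head volume of 0.25 milliliter, a
#' microscopy assay covering all description graphs, a specimen collection
#' with a live trap, and a specimen history that forks into a pinned voucher
#' and a tissue sample.
#'
#' @param pt predicate table.
#' @return list as for [compose_document()].
#' @export
worked_example <- function(pt = default_predicates()) {
  minter <- iri_minter("https://example.org/akg/", seed = 20L)
  organism <- make_instance("organism", "whole organism of specimen A", minter)
  head_i <- make_instance("head", "head of specimen A", minter)
  thorax <- make_instance("thorax", "thorax of specimen A", minter)
  edges <- list(list(parent = organism, child = head_i),
                list(parent = organism, child = thorax))
  qualities <- list(quality_record(thorax, "rough",
                                   "anatomical-surface-texture"))
  measurements <- list(measurement_record(head_i, "volume", 0.25,
                                          "milliliter",
                                          "anatomical-structure-volume"))
  material <- make_instance("material-entity", "leaf litter sample", minter)
  spec_a <- make_instance("specimen", "specimen A", minter)
  collection <- collection_record(
    make_instance("specimen-collection-process", NULL, minter),
    material, spec_a,
    agent = make_instance("person", "field collector", minter),
    device = make_instance("live-trap", "live trap", minter),
    place = make_instance("geographic-place", "type locality", minter),
    date = "2019-05-04")
  spec_b <- make_instance("specimen", "pinned voucher specimen B", minter)
  spec_c <- make_instance("specimen", "tissue sample C", minter)
  steps <- list(processing_step(
    make_instance("material-processing", NULL, minter),
    list(spec_a), list(spec_b, spec_c)))
  assay_specs <- list(list(
    assay = make_instance("microscopy-assay", NULL, minter),
    specimen = spec_b, graphs = 1:5,
    agent = make_instance("person", "observing morphologist", minter),
    device = make_instance("device", "light microscope", minter),
    protocol = make_instance("protocol", "imaging protocol", minter),
    place = make_instance("geographic-place", "collection lab", minter),
    date = "2020-02-11"))
  meta <- document_metadata(
    title = "Morphological description of specimen A",
    sections = stats::setNames(
      c("A worked example description.", rep("", 7)),
      c("abstract", setdiff(SECTION_KEYS, "abstract"))))
  compose_document(meta, organism, edges, qualities, measurements,
                   collection, steps, assay_specs, minter, pt)
}
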