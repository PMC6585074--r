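pt <- default_predicates()

test_that("document graph follows the section scheme with enumerated counts", {
  m <- iri_minter(seed = 3)
  doc <- make_instance("iao-document", NULL, m)
  a_iri <- "https://ex.org/assertions/1"
  g <- build_document_graph(document_metadata(), doc, a_iri, m)
  # 1 doc type + 8 x (section type + has_part) + assertions type + link
  expect_identical(nrow(g$statements), 19L)
  expect_identical(g$ng_class, "document")
  expect_length(attr(g, "sections"), 8L)

  m2 <- iri_minter(seed = 3)
  doc2 <- make_instance("iao-document", NULL, m2)
  meta2 <- document_metadata(sections = c(
    abstract = "Some abstract text.", `author-list` = "", introduction = "",
    `methods-section` = "", `results-section` = "", `discussion-section` = "",
    `conclusion-section` = "", `references-section` = ""))
  g2 <- build_document_graph(meta2, doc2, a_iri, m2)
  expect_identical(nrow(g2$statements), 20L)  # exactly one literal more

  expect_error(document_metadata(sections = c(abstract = "x")),
               class = "akg_scheme_error")
  expect_error(document_metadata(sections = c(`methods-section` = "",
                                              whatever = "")),
               class = "akg_scheme_error")
})

test_that("parthood graphs carry exactly the root / child shapes", {
  m <- iri_minter(seed = 4)
  root <- make_instance("organism", "specimen A whole organism", m)
  g <- build_root_parthood_graph(root, m)
  expect_identical(nrow(g$statements), 2L)
  expect_false(pt[["has_part"]] %in% g$statements$p)

  head_i <- make_instance("head", "head", m)
  g2 <- build_parthood_graph(root, head_i, m)
  expect_identical(nrow(g2$statements), 3L)
  edge <- g2$statements[g2$statements$p == pt[["has_part"]], ]
  expect_identical(edge$s, root$iri)
  expect_identical(edge$o, head_i$iri)

  expect_error(build_parthood_graph(head_i, head_i, m),
               class = "akg_cycle_error")
  unlabeled <- make_instance("thorax", NULL, m)
  expect_error(build_root_parthood_graph(unlabeled, m),
               class = "akg_scheme_error")
  expect_error(build_parthood_graph(root, unlabeled, m),
               class = "akg_scheme_error")

  # two roots never share a subject IRI
  m2 <- iri_minter(seed = 99)
  r2 <- make_instance("organism", "other organism", m2)
  g3 <- build_root_parthood_graph(r2, m2)
  expect_identical(length(intersect(g$statements$s, g3$statements$s)), 0L)

  # union of a root graph and three child graphs over four parts
  kids <- lapply(c("head", "thorax", "abdomen"), function(k) {
    make_instance(k, paste("the", k), m)
  })
  gs <- c(list(g), lapply(kids, function(k) build_parthood_graph(root, k, m)))
  expect_identical(nrow(do.call(st_union, lapply(gs, `[[`, "statements"))),
                   11L)
})

test_that("quality graphs hold one descriptive statement each", {
  m <- iri_minter(seed = 6)
  thorax <- make_instance("thorax", "thorax", m)
  rec <- quality_record(thorax, "rough", "anatomical-surface-texture")
  g <- build_quality_graph(rec, m)
  expect_identical(nrow(g$statements), 2L)
  expect_identical(g$ng_class, "anatomical-surface-texture")

  g2 <- build_quality_graph(rec, m)
  expect_false(g$iri == g2$iri)
  q1 <- g$statements$o[g$statements$p == pt[["has_quality"]]]
  q2 <- g2$statements$o[g2$statements$p == pt[["has_quality"]]]
  expect_false(q1 == q2)  # fresh quality instance per graph

  expect_error(quality_record(thorax, "rough", "colour"),
               class = "akg_catalog_error")
  expect_error(quality_record(thorax, "volume", "anatomical-surface-texture"),
               class = "akg_catalog_error")
})

test_that("measurement graphs hold the five-statement shape", {
  m <- iri_minter(seed = 7)
  head_i <- make_instance("head", "head", m)
  rec <- measurement_record(head_i, "volume", 0.25, "milliliter",
                            "anatomical-structure-volume")
  g <- build_measurement_graph(rec, m)
  expect_identical(nrow(g$statements), 5L)
  val <- g$statements[g$statements$p == pt[["has_value"]], ]
  expect_identical(val$o, "0.25")
  expect_identical(val$o_kind, "literal")
  expect_error(measurement_record(head_i, "volume", NaN, "milliliter",
                                  "anatomical-structure-volume"),
               class = "akg_value_error")
  expect_error(measurement_record(head_i, "volume", Inf, "milliliter",
                                  "anatomical-structure-volume"),
               class = "akg_value_error")
  # units must come from the units ontology
  expect_error(measurement_record(head_i, "volume", 1, "rough",
                                  "anatomical-structure-volume"),
               class = "akg_catalog_error")
  # two measurements of the same bearer share only the bearer IRI
  g2 <- build_measurement_graph(rec, m)
  shared <- intersect(unique(c(g$statements$s, g$statements$o[g$statements$o_kind == "iri"])),
                      unique(c(g2$statements$s, g2$statements$o[g2$statements$o_kind == "iri"])))
  expect_identical(setdiff(shared, c(head_i$iri, term("volume")$iri,
                                     term("milliliter")$iri)), character(0))
})

test_that("assay graphs link specimen input, graph outputs and provenance", {
  m <- iri_minter(seed = 8)
  assay <- make_instance("microscopy-assay", NULL, m)
  spec <- make_instance("specimen", "specimen B", m)
  outs <- c("https://ex.org/g/1", "https://ex.org/g/2")
  rec <- assay_record(assay, spec, outs,
                      agent = make_instance("person", "observer", m),
                      device = make_instance("device", "microscope", m))
  g <- build_assay_graph(rec, m)
  # type + input + 2 outputs + 2 x (instance type + link) = 1 + 1 + 2 + 4
  expect_identical(nrow(g$statements), 8L)

  expect_error(assay_record(assay, spec, character(0)),
               class = "akg_scheme_error")

  stain <- make_instance("material-entity", "staining substance", m)
  rec2 <- assay_record(assay, spec, outs,
                       agent = rec$agent, device = rec$device,
                       extra_inputs = list(stain))
  g2 <- build_assay_graph(rec2, m)
  expect_identical(nrow(g2$statements), nrow(g$statements) + 2L)
})

test_that("collection graphs record one input and one output", {
  m <- iri_minter(seed = 9)
  proc <- make_instance("specimen-collection-process", NULL, m)
  mat <- make_instance("material-entity", "raw material", m)
  spec <- make_instance("specimen", "specimen A", m)
  g <- build_collection_graph(collection_record(proc, mat, spec), m)
  # three type triples + input link + output link
  expect_identical(nrow(g$statements), 5L)
  g2 <- build_collection_graph(collection_record(
    proc, mat, spec, device = make_instance("live-trap", "live trap", m),
    date = "2019-05-04"), m)
  expect_identical(nrow(g2$statements), 5L + 2L + 1L)
})

test_that("specimen histories form DAGs, forks allowed, cycles rejected", {
  m <- iri_minter(seed = 10)
  sp <- function(lbl) make_instance("specimen", lbl, m)
  a <- sp("A"); b <- sp("B"); c_ <- sp("C")
  proc <- function() make_instance("material-processing", NULL, m)
  chain <- list(processing_step(proc(), list(a), list(b)),
                processing_step(proc(), list(b), list(c_)))
  g <- build_history_graph(chain, m)
  ty <- g$statements[g$statements$p == pt[["rdf_type"]], ]
  expect_identical(sum(ty$o == term("specimen")$iri), 3L)
  expect_identical(sum(ty$o == term("material-processing")$iri), 2L)

  fork <- processing_step(proc(), list(a), list(sp("tissue"), sp("voucher")))
  gf <- build_history_graph(list(fork), m)
  outs <- gf$statements[gf$statements$p == pt[["has_specified_output"]], ]
  expect_identical(nrow(outs), 2L)

  cyc <- list(processing_step(proc(), list(a), list(b)),
              processing_step(proc(), list(b), list(a)))
  expect_error(build_history_graph(cyc, m), class = "akg_cycle_error")
  expect_error(processing_step(proc(), list(), list(a)),
               class = "akg_scheme_error")
})

test_that("assertions graph wires sections, anatomy and graphs per scheme", {
  m <- iri_minter(seed = 11)
  res_sec <- make_instance("results-section", NULL, m)
  met_sec <- make_instance("methods-section", NULL, m)
  anatomy <- make_instance("instance-anatomy", NULL, m)
  root <- make_instance("organism", "organism", m)
  desc <- c(list(build_root_parthood_graph(root, m)),
            lapply(1:3, function(i) {
              build_parthood_graph(root,
                                   make_instance("leg", paste("leg", i), m), m)
            }))
  meta <- list(
    build_collection_graph(collection_record(
      make_instance("specimen-collection-process", NULL, m),
      make_instance("material-entity", "mat", m),
      make_instance("specimen", "spec", m)), m),
    build_history_graph(processing_step(
      make_instance("material-processing", NULL, m),
      list(make_instance("specimen", "in", m)),
      list(make_instance("specimen", "out", m))), m))
  ag <- build_assertions_graph(res_sec, met_sec, anatomy, desc, meta,
                               "https://ex.org/assert/1")
  # 2 + 4 description x 2 + 2 metadata x 2
  expect_identical(nrow(ag$statements), 14L)

  expect_error(
    build_assertions_graph(res_sec, met_sec, anatomy, desc, desc[1],
                           "https://ex.org/assert/2"),
    class = "akg_integrity_error")
  # listing the same description graph twice collapses by set semantics
  ag2 <- build_assertions_graph(res_sec, met_sec, anatomy,
                                c(desc, desc[1]), meta,
                                "https://ex.org/assert/3")
  expect_identical(nrow(ag2$statements), 14L)
  expect_error(
    build_assertions_graph(res_sec, met_sec, root, desc, meta,
                           "https://ex.org/assert/4"),
    class = "akg_scheme_error")
})
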