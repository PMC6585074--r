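pt <- default_predicates()

test_that("every builder output validates with zero violations", {
  fx <- worked_example()
  for (iri in graph_iris(fx$store)) {
    rep_g <- validate_named_graph(get_graph(fx$store, iri))
    expect_true(rep_g$passed)
    expect_identical(nrow(rep_g$violations), 0L)
  }
})

test_that("targeted scheme mutations are rejected", {
  fx <- small_description()
  store <- fx$store
  iris <- vapply(fx$description_graphs, `[[`, "", "iri")
  meas_iri <- iris[[6]]
  g <- get_graph(store, meas_iri)
  expect_identical(g$ng_class, "anatomical-structure-volume")

  # missing has_value
  no_val <- g$statements[g$statements$p != pt[["has_value"]], ]
  r <- validate_named_graph(named_graph(g$iri, g$ng_class, no_val))
  expect_false(r$passed)
  expect_true("measurement.one-value" %in% r$violations$rule)

  # a parthood graph with two parthood edges breaks
  # one-descriptive-statement-per-graph
  pg <- get_graph(store, iris[[2]])
  extra <- st_iri("https://ex.org/other-parent", pt[["has_part"]],
                  pg$statements$s[pg$statements$p == pt[["rdfs_label"]]])
  r2 <- validate_named_graph(named_graph(pg$iri, "parthood",
                                         rbind(pg$statements, extra)))
  expect_false(r2$passed)
  expect_true("parthood.single-edge" %in% r2$violations$rule)

  expect_error(
    validate_named_graph(structure(list(iri = "https://x", ng_class = "head",
                                        statements = pg$statements),
                                   class = "named_graph")),
    class = "akg_catalog_error")
})

test_that("document validation passes on complete fixtures", {
  fx <- small_description()
  rep_d <- validate_document(fx$store, fx$doc)
  expect_true(rep_d$passed)
  expect_identical(nrow(rep_d$violations), 0L)
  gen <- generate_description(fixture_config(seed = 21, n_parts = 6))
  expect_true(validate_document(gen$store, gen$doc)$passed)
})

test_that("cross-graph integrity violations are detected", {
  fx <- small_description()
  # deleting a parthood graph from the store leaves a dangling reference
  s2 <- quad_store()
  victim <- fx$description_graphs[[2]]$iri
  for (iri in setdiff(graph_iris(fx$store), victim)) {
    add_graph(s2, get_graph(fx$store, iri))
  }
  r <- validate_document(s2, fx$doc)
  expect_false(r$passed)
  expect_true("doc.dangling-graph" %in% r$violations$rule)

  # assay output pointing at a graph that is not a description graph
  s3 <- clone_store(fx$store)
  assay_iri <- fx$metadata_graphs[[3]]$iri
  ga <- get_graph(s3, assay_iri)
  rogue <- st_iri(ga$statements$s[[1]], pt[["has_specified_output"]],
                  fx$document_graph)
  add_graph(s3, named_graph(assay_iri, "assay-data",
                            rbind(ga$statements, rogue)), replace = TRUE)
  r3 <- validate_document(s3, fx$doc)
  expect_false(r3$passed)
  expect_true("assay.unknown-output" %in% r3$violations$rule)
})

test_that("soft violations surface as warnings, not errors", {
  fx <- small_description()
  # drop the assay graph: description graphs lose documented provenance
  s2 <- quad_store()
  assay_iri <- fx$metadata_graphs[[3]]$iri
  for (iri in setdiff(graph_iris(fx$store), c(assay_iri, fx$assertions_graph))) {
    add_graph(s2, get_graph(fx$store, iri))
  }
  ag <- get_graph(fx$store, fx$assertions_graph)
  keep <- !(ag$statements$s == assay_iri | ag$statements$o == assay_iri)
  add_graph(s2, named_graph(ag$iri, "assertions", ag$statements[keep, ]))
  r <- validate_document(s2, fx$doc)
  expect_true(r$passed)
  expect_true("provenance.unreferenced-graph" %in% r$violations$rule)
  expect_true(all(r$violations$severity[
    r$violations$rule == "provenance.unreferenced-graph"] == "warning"))

  # a second parent for an existing part is only a warning
  s3 <- clone_store(fx$store)
  pu <- parthood_union(s3, fx$anatomy, fx$assertions_graph)
  child <- pu$o[pu$p == pt[["has_part"]]][[1]]
  other <- pu$o[pu$p == pt[["has_part"]]][[2]]
  m <- iri_minter("https://test.example.org/extra/", 1)
  gp <- named_graph(mint_iri(m, "g-parthood"), "parthood", st_union(
    st_iri(child, pt[["rdf_type"]], term("head")$iri),
    st_literal(child, pt[["rdfs_label"]], "relabeled"),
    st_iri(other, pt[["has_part"]], child)))
  add_graph(s3, gp)
  ag3 <- get_graph(s3, fx$assertions_graph)
  add_graph(s3, named_graph(ag3$iri, "assertions", rbind(
    ag3$statements,
    st_iri(fx$anatomy, pt[["has_part"]], gp$iri),
    st_iri(gp$iri, pt[["rdf_type"]], term("parthood")$iri))),
    replace = TRUE)
  r3 <- validate_document(s3, fx$doc)
  expect_true("partonomy.multi-parent" %in% r3$violations$rule)
})

test_that("registered named-graph classes carry their own schemes", {
  register_ng_class("anatomical-structure-colour", "anatomical colour named graph",
                    scheme = "quality", family = "colour")
  register_term("blue", "http://purl.obolibrary.org/obo/PATO_0000318", "blue",
                "pato", "PATO", family = "colour")
  m <- iri_minter(seed = 30)
  eye <- make_instance("eye", "left eye", m)
  g <- build_quality_graph(quality_record(eye, "blue",
                                          "anatomical-structure-colour"), m)
  expect_true(validate_named_graph(g)$passed)
  expect_error(register_ng_class("anatomical-structure-colour", "x", "quality"),
               class = "akg_catalog_error")
  reset_catalog()
})
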