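pt <- default_predicates()

test_that("stores round-trip graphs and count quads", {
  m <- iri_minter(seed = 12)
  root <- make_instance("organism", "org", m)
  g1 <- build_root_parthood_graph(root, m)
  g2 <- build_parthood_graph(root, make_instance("head", "head", m), m)
  store <- quad_store()
  add_graph(store, g1)
  expect_true(st_equal(get_graph(store, g1$iri)$statements, g1$statements))
  expect_error(add_graph(store, g1), class = "akg_collision_error")
  add_graph(store, g1, replace = TRUE)
  add_graph(store, g2)
  expect_identical(nrow(quads(store)),
                   nrow(g1$statements) + nrow(g2$statements))
  expect_error(get_graph(store, "https://ex.org/nope"),
               class = "akg_dangling_error")
})

test_that("pattern search matches the brute-force scan", {
  fx <- small_description()
  store <- fx$store
  # known entry triple finds exactly the document graph
  hits <- find_graphs_containing(store, triple_pattern(
    s = fx$doc, p = pt[["rdf_type"]], o = term("iao-document")$iri))
  expect_identical(hits, fx$document_graph)
  # unmatched pattern
  expect_identical(
    find_graphs_containing(store, triple_pattern(s = "https://ex.org/ghost")),
    character(0))
  # wildcard subject, multiple graphs, sorted, equals oracle
  p_only <- triple_pattern(p = pt[["has_quality"]])
  expect_identical(find_graphs_containing(store, p_only),
                   oracle_find_graphs(store, p = pt[["has_quality"]]))
  expect_error(triple_pattern(), class = "akg_pattern_error")
})

test_that("locate operations find unique anchors and report ambiguity", {
  fx <- small_description()
  store <- fx$store
  expect_identical(locate_document_graph(store, fx$doc), fx$document_graph)
  expect_identical(locate_assertions_graph(store, fx$document_graph),
                   fx$assertions_graph)
  expect_identical(locate_instance_anatomy(store, fx$assertions_graph),
                   fx$anatomy)
  expect_error(locate_document_graph(store, "https://ex.org/ghost"),
               class = "akg_notfound_error")
  # duplicate the document typing in a second graph -> ambiguity
  st <- get_graph(store, fx$document_graph)$statements
  dup <- named_graph("https://ex.org/dup", "unclassified",
                     st[st$p == pt[["rdf_type"]] &
                          st$o == term("iao-document")$iri, ])
  s2 <- clone_store(store)
  add_graph(s2, dup)
  expect_error(locate_document_graph(s2, fx$doc),
               class = "akg_ambiguity_error")
})

test_that("graph unions collapse duplicates and check references", {
  fx <- small_description()
  store <- fx$store
  iris <- vapply(fx$description_graphs, `[[`, "", "iri")
  u2 <- union_graphs(store, iris[1:2])
  expect_identical(nrow(u2),
                   nrow(get_graph(store, iris[1])$statements) +
                     nrow(get_graph(store, iris[2])$statements))
  expect_true(st_equal(union_graphs(store, c(iris[1], iris[1])),
                       get_graph(store, iris[1])$statements))
  expect_error(union_graphs(store, "https://ex.org/ghost"),
               class = "akg_dangling_error")
})

test_that("parthood, description and metadata unions match enumerated counts", {
  fx <- small_description()
  store <- fx$store
  pu <- parthood_union(store, fx$anatomy, fx$assertions_graph)
  expect_identical(nrow(pu), 11L)  # 2 + 3 x 3 over four parts
  du <- description_union(store, fx$anatomy, fx$assertions_graph)
  expect_identical(nrow(du), 18L)  # 11 + 2 (texture) + 5 (volume)
  # parthood union excludes measurement graphs and is a subset
  expect_false(pt[["has_value"]] %in% pu$p)
  expect_identical(nrow(st_union(pu, du)), nrow(du))  # pu is a subset of du
  ms <- locate_section(store, fx$document_graph, "methods-section")
  mu <- metadata_union(store, ms, fx$assertions_graph)
  # set union: the specimen's type triple is shared between the collection
  # and history graphs and collapses
  expect_true(st_equal(mu, do.call(st_union, lapply(fx$metadata_graphs,
                                                    `[[`, "statements"))))
  # metadata shares no part-instance subjects with the description
  expect_identical(intersect(mu$s, pu$s), character(0))
})

test_that("description union restricted to parthood equals parthood union", {
  m <- iri_minter(seed = 13)
  root <- make_instance("organism", "only a root", m)
  res <- compose_document(document_metadata(), root, minter = m)
  pu <- parthood_union(res$store, res$anatomy, res$assertions_graph)
  du <- description_union(res$store, res$anatomy, res$assertions_graph)
  expect_identical(nrow(pu), 2L)
  expect_true(st_equal(pu, du))
})

test_that("partonomy extraction recovers trees and rejects malformed input", {
  fx <- small_description()
  pu <- parthood_union(fx$store, fx$anatomy, fx$assertions_graph)
  po <- extract_partonomy(pu)
  expect_identical(nrow(po$edges), 3L)
  expect_length(po$labels, 4L)
  expect_identical(unname(po$labels[po$root]), "whole organism")

  # single-node tree
  one <- st_union(st_iri("https://ex.org/r", pt[["rdf_type"]], term("organism")$iri),
                  st_literal("https://ex.org/r", pt[["rdfs_label"]], "r"))
  po1 <- extract_partonomy(one)
  expect_identical(po1$root, "https://ex.org/r")
  expect_identical(nrow(po1$edges), 0L)

  cyc <- st_union(st_iri("https://ex.org/a", pt[["has_part"]], "https://ex.org/b"),
                  st_iri("https://ex.org/b", pt[["has_part"]], "https://ex.org/a"))
  expect_error(extract_partonomy(cyc), class = "akg_error")
  two_roots <- st_union(
    st_iri("https://ex.org/a", pt[["has_part"]], "https://ex.org/b"),
    st_iri("https://ex.org/c", pt[["has_part"]], "https://ex.org/d"))
  expect_error(extract_partonomy(two_roots), class = "akg_partonomy_error")
})
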