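# Citation graphs: provenance quads, traversal, verification, rendering.

test_that("an acquisition event emits exactly three well-formed quads", {
  ev <- acquisition_event("https://img.example/bee.jpg", REF$bee_head,
                          started_at = "2021-12-07T10:00:00Z")
  lines <- record_acquisition(ev)
  expect_length(lines, 3L)
  df <- parse_nquads(lines)
  expect_equal(nrow(df), 3L)
  expect_length(attr(df, "skipped"), 0L)
  expect_equal(df$predicate,
               c("http://www.w3.org/ns/prov#used",
                 "http://www.w3.org/ns/prov#generated",
                 "http://www.w3.org/ns/prov#startedAtTime"))
  # graph label is the activity URN, making the acquisition self-describing
  expect_true(all(df$graph == ev$activity_id))
  # round trip: recover (location, signature, time) exactly
  expect_equal(df$object[1], "https://img.example/bee.jpg")
  expect_equal(df$object[2], REF$bee_head)
  expect_equal(df$object[3], "2021-12-07T10:00:00Z")
})

test_that("distinct events carry distinct activity ids", {
  e1 <- acquisition_event("https://a.example/1", compute_signature("1"))
  e2 <- acquisition_event("https://a.example/2", compute_signature("2"))
  expect_false(e1$activity_id == e2$activity_id)
  expect_length(c(record_acquisition(e1), record_acquisition(e2)), 6L)
})

test_that("emitted quads parse with an independent N-Quads reader", {
  ev <- acquisition_event("https://img.example/bee.jpg", REF$bee_head,
                          started_at = "2021-12-07T10:00:00Z",
                          activity_id = "urn:uuid:00000000-0000-4000-8000-000000000001")
  claim <- assert_relation(REF$wing_a, "different-from", REF$wing_b,
                           claim_id = "urn:uuid:00000000-0000-4000-8000-000000000002")
  nq <- withr::local_tempfile(fileext = ".nq")
  writeLines(c(record_acquisition(ev), claim), nq)
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(paste0(
      "import sys, rdflib; g = rdflib.Dataset(); g.parse('", nq,
      "', format='nquads'); print(len(list(g.quads((None,None,None,None)))))"
    ))), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    fail(paste("independent N-Quads reader rejected the output:",
               paste(out, collapse = " ")))
  }
  expect_equal(tail(out, 1), "4")
})

test_that("a two-leaf collection builds a 3-node, 2-edge graph", {
  fx <- make_corpus(depth = 2, fanout = 2, seed = 7)
  g <- build_graph(fx$corpus$root, store_resolver(fx$store))
  expect_length(g$nodes, 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(nrow(g$unresolved), 0L)
  expect_equal(g$nodes[1], format(fx$corpus$root))
  expect_setequal(g$edges$referenced, fx$corpus$leaves)
})

test_that("the depth-3 fanout-3 corpus builds 13 nodes and 12 edges", {
  fx <- make_corpus(depth = 3, fanout = 3, seed = 42)
  g <- build_graph(fx$corpus$root, store_resolver(fx$store))
  expect_length(g$nodes, 13L)
  expect_equal(nrow(g$edges), 12L)
  expect_equal(nrow(g$unresolved), 0L)
  # both citation media appear
  expect_setequal(unique(g$edges$medium), c("text", "rdf"))
  # rebuilding yields the identical node and edge sets
  g2 <- build_graph(fx$corpus$root, store_resolver(fx$store))
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$edges, g2$edges)
})

test_that("missing leaves land in unresolved and traversal continues", {
  fx <- make_corpus(depth = 2, fanout = 2, seed = 7)
  missing <- fx$corpus$leaves[1]
  path <- signcite:::store_path(fx$store,
                                parse_signature(missing)$payload)
  unlink(path)
  g <- build_graph(fx$corpus$root, store_resolver(fx$store))
  expect_equal(g$unresolved$signature, missing)
  expect_equal(g$unresolved$reason, "not-found")
  # the sibling is still reached
  expect_true(fx$corpus$leaves[2] %in% g$nodes)
  # an unresolvable root gives an empty graph with the root unresolved
  empty_store <- content_store(withr::local_tempdir())
  g0 <- build_graph(fx$corpus$root, store_resolver(empty_store))
  expect_length(g0$nodes, 0L)
  expect_equal(g0$unresolved$signature, format(fx$corpus$root))
})

test_that("an untampered graph verifies fully; each corrupted leaf is flagged exactly", {
  fx <- make_corpus(depth = 3, fanout = 3, seed = 42)
  resolver <- store_resolver(fx$store)
  rep0 <- verify_graph(fx$corpus$root, resolver)
  expect_equal(unname(rep0$counts["verified"]), 13L)
  expect_equal(sum(rep0$counts), 13L)
  for (leaf in fx$corpus$leaves) {
    sig <- parse_signature(leaf)$payload
    path <- signcite:::store_path(fx$store, sig)
    original <- readBin(path, "raw", n = file.size(path))
    tampered <- original
    tampered[1] <- xor(tampered[1], as.raw(1))
    writeBin(tampered, path)
    rep <- verify_graph(fx$corpus$root, resolver)
    expect_equal(unname(rep$counts["drifted"]), 1L)
    expect_equal(rep$nodes$signature[rep$nodes$status == "drifted"], leaf)
    expect_equal(unname(rep$counts["verified"]), 12L)
    writeBin(original, path)
  }
})

test_that("reference lists round-trip the leaf signatures and repackage", {
  fx <- make_corpus(depth = 2, fanout = 2, seed = 7)
  g <- build_graph(fx$corpus$root, store_resolver(fx$store))
  refs <- render_reference_list(g)
  expect_length(refs, 2L)
  got <- unlist(lapply(refs, function(r)
    vapply(extract_signatures(r), function(p) format(p$payload),
           character(1))))
  expect_equal(got, fx$corpus$leaves)
  # placeholder fields appear when no metadata is supplied
  expect_true(all(grepl("^Unknown creator\\. n\\.d\\. Untitled content ",
                        refs)))
  # with metadata, the supplied fields are used
  md <- function(uri) list(creators = "Museum X", date = "2021",
                           title = "An image")
  refs2 <- render_reference_list(g, md)
  expect_true(all(startsWith(refs2, "Museum X. 2021. An image hash://")))
  # the rendered list is itself packageable into a new signed collection
  coll <- package_collection(refs)
  expect_s3_class(coll$signature, "content_signature")
})

test_that("tally_resources counts distinct matching IRIs and skips junk lines", {
  ctx <- "urn:uuid:00000000-0000-4000-8000-00000000000a"
  mk <- function(i) sprintf(
    "<https://search.example/v2/view/mediarecords/%d> <http://www.w3.org/ns/prov#used> <urn:x:%d> <%s> .",
    i, i, ctx)
  quads <- c(mk(1), mk(2), mk(3), mk(1), mk(2), mk(3))  # 3 distinct, twice each
  n <- tally_resources(quads, "search\\.example/v2/view/mediarecords/")
  expect_equal(as.integer(n), 3L)
  expect_equal(as.integer(tally_resources("", "anything")), 0L)
  withjunk <- c(mk(1), "this is not a quad", mk(2))
  n2 <- tally_resources(withjunk, "mediarecords")
  expect_equal(as.integer(n2), 2L)
  expect_length(attr(n2, "skipped"), 1L)
})

test_that("relation claims link signatures without altering identity", {
  lines <- assert_relation(REF$wing_a, "different-from", REF$wing_b)
  df <- parse_nquads(lines)
  expect_equal(df$subject, REF$wing_a)
  expect_equal(df$object, REF$wing_b)
  expect_equal(df$predicate, "http://www.w3.org/2002/07/owl#differentFrom")
  # reflexive same-as is valid
  expect_no_error(assert_relation(REF$wing_a, "same-as", REF$wing_a))
  # different-from of a signature with itself is a contradiction
  expect_error(assert_relation(REF$wing_a, "different-from", REF$wing_a),
               class = "signcite_contradiction")
  # custom relation IRIs pass through; prefixes are rejected
  custom <- assert_relation(REF$wing_a, "https://vocab.example/depictsSameSpecimen",
                            REF$wing_b)
  expect_equal(parse_nquads(custom)$predicate,
               "https://vocab.example/depictsSameSpecimen")
  expect_error(assert_relation(REF$readable16, "same-as", REF$wing_b),
               class = "signcite_validation_error")
})
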