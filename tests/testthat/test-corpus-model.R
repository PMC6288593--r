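test_that("standoff entity lines parse with verified offsets", {
  td <- withr::local_tempdir()
  writeLines("Renal Failure", file.path(td, "a.txt"), sep = "")
  writeLines("T1\tSSLIF 0 13\tRenal Failure", file.path(td, "a.ann"))
  doc <- read_standoff(file.path(td, "a.txt"))
  expect_equal(nrow(doc$entities), 1L)
  expect_equal(doc$entities$start, 0L)
  expect_equal(doc$entities$end, 13L)
  expect_equal(doc$entities$type, "SSLIF")
  expect_equal(doc$entities$text, "Renal Failure")
})

test_that("malformed and inconsistent annotation files are rejected", {
  td <- withr::local_tempdir()
  writeLines("Renal Failure", file.path(td, "a.txt"), sep = "")
  # dangling relation argument
  writeLines(c("T1\tSSLIF 0 13\tRenal Failure",
               "R1\tSeverity-ADE Arg1:T9 Arg2:T1"),
             file.path(td, "a.ann"))
  expect_error(read_standoff(file.path(td, "a.txt")), "T9")
  # surface/offset mismatch
  writeLines("T1\tSSLIF 0 5\tRenal Failure", file.path(td, "a.ann"))
  expect_error(read_standoff(file.path(td, "a.txt")), "mismatch")
  # malformed line carries its line number
  writeLines(c("T1\tSSLIF 0 13\tRenal Failure", "garbage line"),
             file.path(td, "a.ann"))
  expect_error(read_standoff(file.path(td, "a.txt")), "line 2")
  # offsets out of range
  writeLines("T1\tSSLIF 0 99\tRenal Failure", file.path(td, "a.ann"))
  expect_error(read_standoff(file.path(td, "a.txt")), "range")
})

test_that("write/read round trip is the identity on documents", {
  td <- withr::local_tempdir()
  d <- tiny_doc()
  write_standoff(d, td)
  d2 <- read_standoff(file.path(td, "d1.txt"))
  expect_identical(d$text, d2$text)
  expect_equal(d$entities, d2$entities)
  expect_equal(d$relations, d2$relations)
  # empty document -> text file plus empty annotation file
  e <- ade_document("empty", "No findings .")
  paths <- write_standoff(e, td)
  expect_identical(length(readLines(paths[["ann_path"]])), 0L)
  e2 <- read_standoff(paths[["text_path"]])
  expect_equal(nrow(e2$entities), 0L)
  # annotation line count: 2 entities + 1 relation -> 3 lines
  d3 <- ade_document("d3", "Zalprex for cardelia",
    entities = tibble::tibble(id = c("T1", "T2"),
                              type = c("Medication", "Indication"),
                              start = c(0L, 12L), end = c(7L, 20L),
                              text = c("Zalprex", "cardelia")),
    relations = tibble::tibble(id = "R1", type = "Medication-Indication",
                               arg1 = "T1", arg2 = "T2"))
  p3 <- write_standoff(d3, td)
  expect_identical(length(readLines(p3[["ann_path"]])), 3L)
})

test_that("generated corpora round-trip losslessly through standoff files", {
  corpus <- small_corpus(n_docs = 50L, seed = 11L)
  docs <- c(corpus$train, corpus$test)
  td <- withr::local_tempdir()
  write_standoff_dir(docs, td)
  back <- read_standoff_dir(td)
  expect_length(back, length(docs))
  ord <- order(vapply(docs, `[[`, "", "doc_id"))
  for (i in seq_along(back)) {
    a <- docs[[ord[i]]]
    b <- back[[i]]
    expect_identical(a$text, b$text)
    expect_equal(a$entities, b$entities)
    expect_equal(a$relations, b$relations)
  }
})

test_that("schema validation flags exactly the violations", {
  d <- tiny_doc()
  expect_identical(nrow(validate_schema(d)), 0L)
  # Severity-ADE with correct signature: no violation
  t2 <- "mild nausea"
  ok <- ade_document("s", t2,
    entities = tibble::tibble(id = c("T1", "T2"),
                              type = c("Severity", "ADE"),
                              start = c(0L, 5L), end = c(4L, 11L),
                              text = c("mild", "nausea")),
    relations = tibble::tibble(id = "R1", type = "Severity-ADE",
                               arg1 = "T1", arg2 = "T2"))
  expect_identical(nrow(validate_schema(ok)), 0L)
  # wrong arg2 type -> one violation
  bad <- ade_document("s", t2,
    entities = tibble::tibble(id = c("T1", "T2"),
                              type = c("Severity", "Medication"),
                              start = c(0L, 5L), end = c(4L, 11L),
                              text = c("mild", "nausea")),
    relations = tibble::tibble(id = "R1", type = "Severity-ADE",
                               arg1 = "T1", arg2 = "T2"))
  v <- validate_schema(bad)
  expect_identical(nrow(v), 1L)
  expect_identical(v$kind, "argument_type")
  # unknown entity type -> one violation
  unk <- ade_document("s", t2,
    entities = tibble::tibble(id = "T1", type = "Drug", start = 0L,
                              end = 4L, text = "mild"))
  v2 <- validate_schema(unk)
  expect_identical(nrow(v2), 1L)
  expect_identical(v2$kind, "entity_type")
})

test_that("document invariants are enforced at construction", {
  expect_error(ade_document("x", "abc",
    entities = tibble::tibble(id = "T1", type = "ADE", start = 0L, end = 9L,
                              text = "abc")), "range")
  expect_error(ade_document("x", "abc def",
    entities = tibble::tibble(id = "T1", type = "ADE", start = 0L, end = 3L,
                              text = "zzz")), "substring")
  expect_error(ade_document("x", "abc",
    entities = tibble::tibble(id = c("T1", "T1"), type = c("ADE", "ADE"),
                              start = c(0L, 0L), end = c(3L, 3L),
                              text = c("abc", "abc"))), "duplicate")
})
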