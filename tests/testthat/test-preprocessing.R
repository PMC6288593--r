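test_that("tokenizer records exact offsets and capitalisation", {
  tk <- tokenize_text("Renal Failure.")
  expect_equal(tk$text, c("Renal", "Failure", "."))
  expect_equal(tk$initial_capital, c(TRUE, TRUE, FALSE))
  # offsets round-trip for arbitrary text
  txt <- "Started Zalprex 50 mg orally, twice daily for 2 weeks. He's fine."
  tk2 <- tokenize_text(txt)
  expect_equal(substring(txt, tk2$start + 1L, tk2$end), tk2$text)
  expect_true(all(diff(tk2$start) > 0))
  # empty text -> zero tokens
  expect_identical(nrow(tokenize_text("")), 0L)
})

test_that("sentence splitting breaks at sentence-final punctuation", {
  tk <- tokenize_text("First one . Second one .")
  expect_equal(unique(tk$sentence_index[tk$text == "Second"]), 2L)
  expect_identical(max(tk$sentence_index), 2L)
})

test_that("rule-based tagger is deterministic and covers the examples", {
  expect_equal(rule_pos_tag("Renal"), "JJ")
  expect_equal(rule_pos_tag("50"), "CD")
  expect_equal(rule_pos_tag("2.5"), "CD")
  expect_equal(rule_pos_tag("."), ".")
  s <- c("Patient", "developed", "severe", "nausea", "after", "Zalprex")
  expect_identical(rule_pos_tag(s), rule_pos_tag(s))
})

test_that("BMES coding covers multi-token, single-token and O labels", {
  d <- tiny_doc()
  tk <- tokenize_text(d$text)
  sents <- split(tk, tk$sentence_index)
  l1 <- encode_bmes(sents[[1]], d$entities)
  # "Zalprex" single-token Medication; "50 mg" two-token Dosage
  expect_equal(l1[3:5], c("S_Medication", "B_Dosage", "E_Dosage"))
  expect_equal(l1[1:2], c("O", "O"))
  l2 <- encode_bmes(sents[[2]], d$entities)
  expect_equal(sum(l2 != "O"), 2L)
  # two-token entity of one type -> [B_t, E_t]
  txt <- "Renal Failure"
  tk2 <- tokenize_text(txt)
  ents <- tibble::tibble(id = "T1", type = "SSLIF", start = 0L, end = 13L,
                         text = txt)
  expect_equal(as.vector(encode_bmes(tk2, ents)), c("B_SSLIF", "E_SSLIF"))
})

test_that("overlapping entities are an error; misaligned spans snap outward", {
  txt <- "Renal Failure"
  tk <- tokenize_text(txt)
  over <- tibble::tibble(id = c("T1", "T2"), type = c("SSLIF", "ADE"),
                         start = c(0L, 6L), end = c(13L, 13L),
                         text = c("Renal Failure", "Failure"))
  expect_error(encode_bmes(tk, over), "overlap")
  part <- tibble::tibble(id = "T1", type = "SSLIF", start = 2L, end = 9L,
                         text = "nal Fai")
  lab <- encode_bmes(tk, part)
  expect_equal(as.vector(lab), c("B_SSLIF", "E_SSLIF"))
  expect_identical(attr(lab, "snapped"), 1L)
})

test_that("encode and decode BMES are mutually inverse on aligned spans", {
  set.seed(42)
  types <- ade_entity_types()
  for (rep in 1:50) {
    n <- sample(3:12, 1L)
    words <- replicate(n, paste(sample(letters, 4), collapse = ""))
    txt <- paste(words, collapse = " ")
    tk <- tokenize_text(txt)
    # random non-overlapping aligned spans
    ents <- empty_entities()
    i <- 1L
    while (i <= n) {
      if (stats::runif(1) < 0.4) {
        len <- min(sample(1:3, 1L), n - i + 1L)
        ents <- dplyr::bind_rows(ents, tibble::tibble(
          id = paste0("T", nrow(ents) + 1L), type = sample(types, 1L),
          start = tk$start[i], end = tk$end[i + len - 1L],
          text = substring(txt, tk$start[i] + 1L, tk$end[i + len - 1L])))
        i <- i + len
      } else {
        i <- i + 1L
      }
    }
    labs <- encode_bmes(tk, ents)
    dec <- decode_bmes(as.vector(labs), tk, text = txt)
    expect_equal(dec$start, ents$start)
    expect_equal(dec$end, ents$end)
    expect_equal(dec$type, ents$type)
    # re-encoding the decoded spans reproduces the labels
    dec$id <- paste0("T", seq_len(nrow(dec)))
    expect_equal(as.vector(encode_bmes(tk, dec)), as.vector(labs))
  }
})

test_that("ill-formed label sequences are repaired deterministically", {
  tk <- tokenize_text("a b c")
  dec <- function(labs) decode_bmes(labs, tk[seq_along(labs), ])
  # frozen hand cases
  expect_identical(nrow(dec(c("O", "M_ADE", "O"))), 0L)
  expect_identical(nrow(dec(c("O", "E_ADE", "O"))), 0L)
  d1 <- dec(c("B_ADE", "O", "O")) # lone B -> single-token entity
  expect_identical(nrow(d1), 1L)
  expect_equal(d1$start, 0L)
  d2 <- dec(c("S_ADE", "S_SSLIF", "O")) # adjacent singletons
  expect_identical(nrow(d2), 2L)
  d3 <- dec(c("B_ADE", "M_ADE", "O")) # truncated run covers B..M
  expect_identical(nrow(d3), 1L)
  expect_equal(d3$end, tk$end[2])
  d4 <- dec(c("B_ADE", "M_SSLIF", "O")) # type switch: B alone, M orphan
  expect_identical(nrow(d4), 1L)
  expect_equal(d4$end, tk$end[1])
  # exhaustive agreement with an independent transcription of the rule,
  # all patterns of length <= 3 over two entity types
  alpha <- c("O", paste0(rep(c("B", "M", "E", "S"), 2), "_",
                         rep(c("ADE", "SSLIF"), each = 4)))
  for (len in 1:3) {
    grid <- expand.grid(rep(list(alpha), len), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      labs <- as.character(grid[r, ])
      got <- dec(labs)
      ref <- reference_decode(labs)
      expect_identical(nrow(got), length(ref))
      if (length(ref) > 0) {
        expect_equal(got$start, tk$start[vapply(ref, `[[`, 0L, 1L)])
        expect_equal(got$end, tk$end[vapply(ref, `[[`, 0L, 2L)])
        expect_equal(got$type, vapply(ref, `[[`, "", 3L))
      }
    }
  }
})

test_that("candidate generation is complete, typed, and gap-bounded", {
  d <- tiny_doc()
  cand <- build_relation_candidates(d, max_sentence_gap = 3L)
  # all three gold pairs present with their labels
  expect_setequal(cand$label[cand$label != "None"],
                  c("Dosage-Medication", "Medication-Indication",
                    "Medication-ADE"))
  # no type-incompatible pair ever appears
  sig <- ade_relation_types()
  key <- paste(pmin(cand$e1_type, cand$e2_type),
               pmax(cand$e1_type, cand$e2_type))
  skey <- paste(pmin(sig$arg1_type, sig$arg2_type),
                pmax(sig$arg1_type, sig$arg2_type))
  expect_true(all(key %in% skey))
  # sentence gap 0 excludes the cross-sentence Medication/ADE pairing
  cand0 <- build_relation_candidates(d, max_sentence_gap = 0L)
  expect_true(all(cand0$sent_gap == 0L))
  # 2 Medications x 2 ADEs in one sentence -> 4 candidates
  txt <- "Zalprex and Cortivan caused nausea and tremor ."
  ents <- tibble::tibble(
    id = paste0("T", 1:4),
    type = c("Medication", "Medication", "ADE", "ADE"),
    start = c(0L, 12L, 28L, 39L), end = c(7L, 20L, 34L, 45L),
    text = c("Zalprex", "Cortivan", "nausea", "tremor"))
  d2 <- ade_document("x", txt, ents)
  expect_identical(nrow(build_relation_candidates(d2)), 4L)
  # brute-force pair enumeration agrees on generated documents
  corpus <- small_corpus(n_docs = 6L, seed = 3L)
  for (doc in corpus$train) {
    cand <- build_relation_candidates(doc, max_sentence_gap = 10L)
    gold <- doc$relations
    got <- sum(cand$label != "None")
    expect_identical(got, nrow(gold)) # completeness at large gap
  }
})

test_that("position features follow the signed-distance convention", {
  cand <- tibble::tibble(win_from = 1L, win_to = 10L, e1_from = 3L,
                         e1_to = 4L, e2_from = 8L, e2_to = 9L)
  p <- compute_positions(cand, max_position = 30L)
  expect_equal(p$positions1[2], -1L) # immediately before e1
  expect_equal(p$positions1[3], 0L)  # first token of e1
  expect_equal(p$positions1[6], 2L)  # idx 6: +2 after e1 (ends at 4)
  expect_equal(p$positions2[6], -2L) # idx 6: -2 before e2 (starts at 8)
  # clipping at +/- max_position
  pc <- compute_positions(cand, max_position = 1L)
  expect_true(all(abs(c(pc$positions1, pc$positions2)) <= 1L))
})

test_that("distance buckets follow the {0,1,2,3-5,6-10,>10} rule", {
  expect_equal(adex:::distance_bucket(c(0L, 1L, 2L, 3L, 5L, 6L, 7L, 10L,
                                        11L, 40L)),
               c(0L, 1L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L))
})
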