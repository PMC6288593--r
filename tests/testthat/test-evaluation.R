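# Greedy one-to-one matching oracle used to cross-check the count-based
# implementation: each prediction consumes at most one identical gold item.
oracle_counts <- function(gold_keys, pred_keys) {
  used <- rep(FALSE, length(gold_keys))
  tp <- 0L
  for (p in pred_keys) {
    hit <- which(!used & gold_keys == p)
    if (length(hit) > 0) {
      used[hit[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(pred_keys) - tp, fn = length(gold_keys) - tp)
}

test_that("micro P/R/F1 reproduces hand-computed fixtures", {
  fixtures <- list(
    list(tp = 3, fp = 1, fn = 2, p = 0.75, r = 0.6, f = 2 * .75 * .6 / 1.35),
    list(tp = 0, fp = 0, fn = 0, p = 0, r = 0, f = 0), # 0/0 convention
    list(tp = 0, fp = 5, fn = 0, p = 0, r = 0, f = 0),
    list(tp = 0, fp = 0, fn = 7, p = 0, r = 0, f = 0),
    list(tp = 10, fp = 0, fn = 0, p = 1, r = 1, f = 1),
    list(tp = 1, fp = 1, fn = 1, p = 0.5, r = 0.5, f = 0.5),
    list(tp = 8, fp = 2, fn = 8, p = 0.8, r = 0.5, f = 2 * .8 * .5 / 1.3),
    list(tp = 2, fp = 6, fn = 2, p = 0.25, r = 0.5, f = 2 * .25 * .5 / .75),
    list(tp = 99, fp = 1, fn = 0, p = 0.99, r = 1, f = 2 * .99 / 1.99),
    list(tp = 5, fp = 5, fn = 15, p = 0.5, r = 0.25, f = 2 * .5 * .25 / .75),
    list(tp = 7, fp = 3, fn = 7, p = 0.7, r = 0.5, f = 2 * .7 * .5 / 1.2)
  )
  for (fx in fixtures) {
    m <- micro_prf(tibble::tibble(tp = fx$tp, fp = fx$fp, fn = fx$fn))
    expect_equal(m$precision, fx$p)
    expect_equal(m$recall, fx$r)
    expect_equal(m$f1, fx$f)
  }
})

test_that("micro-averaging differs from macro-averaging as it must", {
  counts <- tibble::tibble(type = c("A", "B"),
                           tp = c(90L, 1L), fp = c(10L, 9L), fn = c(10L, 9L))
  micro <- micro_prf(counts)$f1
  f1_of <- function(i) micro_prf(counts[i, ])$f1
  macro <- mean(c(f1_of(1), f1_of(2)))
  expect_equal(micro, 91 / 110) # P = R = F1 from summed counts
  expect_equal(macro, (0.9 + 0.1) / 2)
  expect_gt(abs(micro - macro), 0.3)
})

test_that("entity matching is exact-span and consumes each gold once", {
  d <- tiny_doc()
  # identical lists: no errors
  c0 <- match_entities(list(d), list(d))
  m0 <- micro_prf(c0)
  expect_equal(c(m0$fp, m0$fn), c(0, 0))
  expect_equal(m0$f1, 1)
  # off-by-one span counts as both fp and fn
  shift <- d
  shift$entities$start[1] <- shift$entities$start[1] + 1L
  shift$entities$end[1] <- shift$entities$end[1] + 1L
  shift$entities$text[1] <- adex:::substr_many(d$text,
                                               shift$entities$start[1],
                                               shift$entities$end[1])
  ms <- micro_prf(match_entities(list(d), list(shift)))
  expect_equal(ms$fp, 1)
  expect_equal(ms$fn, 1)
  # swapping gold and prediction swaps precision and recall
  half <- d
  half$entities <- half$entities[1:2, ]
  half$relations <- adex:::empty_relations()
  a <- micro_prf(match_entities(list(d), list(half)))
  b <- micro_prf(match_entities(list(half), list(d)))
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
})

test_that("entity matching agrees with the greedy one-to-one oracle", {
  set.seed(71)
  types <- ade_entity_types()
  for (rep in 1:25) {
    n <- 30L
    text <- paste(rep("word", n * 2L), collapse = " ")
    mk <- function(k) {
      starts <- sample(seq(0L, (2L * n - 1L) * 5L, by = 5L), k)
      tibble::tibble(id = paste0("T", seq_len(k)),
                     type = sample(types[1:3], k, replace = TRUE),
                     start = starts, end = starts + 4L,
                     text = rep("word", k))
    }
    g <- ade_document("d", text, mk(sample(3:8, 1L)))
    p <- ade_document("d", text, mk(sample(3:8, 1L)))
    counts <- match_entities(list(g), list(p))
    key <- function(e) paste(e$start, e$end, e$type)
    o <- oracle_counts(key(g$entities), key(p$entities))
    expect_equal(sum(counts$tp), unname(o["tp"]))
    expect_equal(sum(counts$fp), unname(o["fp"]))
    expect_equal(sum(counts$fn), unname(o["fn"]))
  }
})

test_that("relation matching requires exact argument spans and types", {
  d <- tiny_doc()
  perfect <- micro_prf(match_relations(list(d), list(d)))
  expect_equal(perfect$f1, 1)
  # correct type, one argument span wrong: fp + fn
  wrong <- d
  wrong$entities$start[2] <- 25L
  wrong$entities$text[2] <- adex:::substr_many(d$text, 25L,
                                               wrong$entities$end[2])
  m <- match_relations(list(d), list(wrong))
  row <- m[m$type == "Dosage-Medication", ]
  expect_equal(row$fp, 1L)
  expect_equal(row$fn, 1L)
  # exhaustive pairwise comparison oracle on documents with <= 10 relations
  set.seed(72)
  corpus <- small_corpus(n_docs = 5L, seed = 73L)
  for (doc in corpus$train) {
    if (nrow(doc$relations) == 0 || nrow(doc$relations) > 10) next
    pred <- doc
    keep <- sample(nrow(doc$relations),
                   max(0L, nrow(doc$relations) - 1L))
    pred$relations <- pred$relations[keep, ]
    counts <- match_relations(list(doc), list(pred))
    rg <- adex:::resolved_relations(list(doc))
    rp <- adex:::resolved_relations(list(pred))
    o <- oracle_counts(rg$key, if (is.null(rp)) character(0) else rp$key)
    expect_equal(sum(counts$tp), unname(o["tp"]))
    expect_equal(sum(counts$fp), unname(o["fp"]))
    expect_equal(sum(counts$fn), unname(o["fn"]))
  }
  # dangling argument ids are an error
  broken <- list(doc_id = "b", text = d$text, entities = d$entities[1:2, ],
                 relations = d$relations, split = "none")
  class(broken) <- "ade_document"
  expect_error(match_relations(list(d), list(broken)), "dangling")
})

test_that("per-type rows recompose into the micro-averaged total", {
  counts <- tibble::tibble(type = c("A", "B", "C"),
                           tp = c(5L, 0L, 2L), fp = c(1L, 3L, 0L),
                           fn = c(2L, 1L, 4L))
  tab <- adex:::prf_table(counts)
  all_row <- tab[tab$type == "ALL", ]
  expect_equal(all_row$tp, sum(counts$tp))
  expect_equal(all_row$precision, 7 / 11)
  expect_equal(all_row$recall, 7 / 14)
  for (t in counts$type) {
    expect_equal(tab$tp[tab$type == t], counts$tp[counts$type == t])
  }
})
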