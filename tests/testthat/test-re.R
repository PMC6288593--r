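make_re_fixture <- function() {
  vocab <- list(word = c("<unk>", "zalprex", "nausea", "after", "mg"),
                pos = c("<unk>", "NN", "CD"),
                types = ade_entity_types(), labels = relation_labels())
  cfg <- re_config(word_dim = 6L, pos_dim = 3L, position_dim = 4L,
                   max_position = 8L, lstm_hidden = 8L, attention_dim = 6L,
                   type_dim = 3L, dist_dim = 3L, count_dim = 3L, dropout = 0)
  set.seed(31)
  params <- adex:::re_init_params(cfg, vocab)
  inst <- list(widx = c(2L, 4L, 3L), pidx = c(2L, 2L, 2L),
               d1 = c(9L, 10L, 11L), d2 = c(7L, 8L, 9L),
               e1_widx = 2L, e2_widx = 3L, t1 = 1L, t2 = 8L,
               dist = 2L, count = 1L, yidx = 6L)
  list(vocab = vocab, cfg = cfg, params = params, inst = inst)
}

test_that("attention weights are a proper, shift-invariant distribution", {
  fx <- make_re_fixture()
  set.seed(32)
  h_val <- matrix(rnorm(40), 5L, 8L)
  adex:::ad_tape_begin()
  att <- adex:::attention_run(fx$params, "re.attn", adex:::ad_const(h_val))
  w <- att$weights$val
  ctx <- att$context$val
  adex:::ad_tape_end()
  expect_equal(sum(w), 1, tolerance = 1e-6)
  expect_true(all(w >= 0))
  expect_identical(dim(ctx), c(1L, 8L))
  # identical rows -> uniform weights
  adex:::ad_tape_begin()
  att_u <- adex:::attention_run(fx$params, "re.attn",
                                adex:::ad_const(h_val[c(1, 1, 1, 1), ]))
  adex:::ad_tape_end()
  expect_equal(as.vector(att_u$weights$val), rep(0.25, 4L))
  # adding a constant to all scores does not move the weights
  sc <- tanh(sweep(h_val %*% fx$params[["re.attn.W"]], 2L,
                   -fx$params[["re.attn.b"]], "-")) %*%
    fx$params[["re.attn.v"]]
  soft <- function(x) exp(x - max(x)) / sum(exp(x - max(x)))
  expect_equal(as.vector(w), as.vector(soft(sc)), tolerance = 1e-9)
  expect_equal(soft(sc + 5), soft(sc), tolerance = 1e-12)
})

test_that("a two-row hand case reproduces the softmax-weighted sum", {
  params <- list("a.W" = diag(2), "a.b" = matrix(0, 1L, 2L),
                 "a.v" = matrix(c(1, 0), 2L, 1L))
  h <- matrix(c(0.5, 0, -0.5, 0), 2L, 2L, byrow = TRUE)
  adex:::ad_tape_begin()
  att <- adex:::attention_run(params, "a", adex:::ad_const(h))
  adex:::ad_tape_end()
  s <- tanh(h) %*% matrix(c(1, 0), 2L, 1L) # scores tanh(0.5), tanh(-0.5)
  w <- exp(s - max(s)); w <- w / sum(w)
  expect_equal(as.vector(att$weights$val), as.vector(w), tolerance = 1e-12)
  expect_equal(att$context$val, t(w) %*% h, tolerance = 1e-12)
})

test_that("side features encode adjacency and between-entity counts", {
  txt <- "Zalprex 50 mg and nausea then Cortivan"
  ents <- tibble::tibble(
    id = paste0("T", 1:3),
    type = c("Medication", "Dosage", "ADE"),
    start = c(0L, 8L, 18L), end = c(7L, 13L, 24L),
    text = c("Zalprex", "50 mg", "nausea"))
  d <- ade_document("x", txt, ents)
  cand <- build_relation_candidates(d)
  adj <- cand[cand$e1 == "T1" & cand$e2 == "T2", ]
  expect_equal(adj$token_distance, 0L) # adjacent entities
  expect_equal(adj$entity_count_between, 0L)
  far <- cand[cand$e1 == "T1" & cand$e2 == "T3", ]
  expect_equal(far$entity_count_between, 1L) # the dosage lies between
})

test_that("class probabilities sum to one over the 8 labels", {
  fx <- make_re_fixture()
  model <- structure(list(params = fx$params, vocab = fx$vocab,
                          config = fx$cfg, trained = TRUE),
                     class = "ade_re")
  p <- adex:::re_classify_instance(model, fx$inst)
  expect_length(p, 8L)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
})

shared_re_fit <- function() {
  cached("re_fit_8_41", {
    corpus <- small_corpus(n_docs = 8L, seed = 41L)
    list(corpus = corpus,
         fit = re_fit(corpus$train, fast_re_cfg(epochs = 4L, seed = 4L)))
  })
}

test_that("training reduces the cross-entropy on a toy instance set", {
  fit <- shared_re_fit()$fit
  lg <- tidy(fit)
  expect_lt(lg$loss[nrow(lg)], lg$loss[1L] / 2)
})

test_that("relation extraction respects the schema and typing", {
  corpus <- shared_re_fit()$corpus
  fit <- shared_re_fit()$fit
  # no type-compatible pairs -> no relations
  txt <- "History of nausea and tremor ."
  d0 <- ade_document("z", txt, tibble::tibble(
    id = c("T1", "T2"), type = c("SSLIF", "SSLIF"),
    start = c(11L, 22L), end = c(17L, 28L), text = c("nausea", "tremor")))
  expect_identical(nrow(extract_relations(fit, d0)$relations), 0L)
  # predictions always satisfy the 7 signatures
  for (doc in corpus$test) {
    gold_ents <- adex:::set_annotations(doc,
                                        relations = adex:::empty_relations())
    pred <- extract_relations(fit, gold_ents)
    expect_identical(nrow(validate_schema(pred)), 0L)
  }
  # untrained model errors
  fake <- structure(list(trained = FALSE), class = "ade_re")
  expect_error(extract_relations(fake, tiny_doc()), "trained")
})

test_that("classification ignores entities outside the candidate window", {
  fit <- shared_re_fit()$fit
  txt1 <- "Zalprex caused nausea ."
  txt2 <- "Zalprex caused nausea . History of tremor ."
  mk <- function(txt, extra) {
    ents <- tibble::tibble(
      id = c("T1", "T2"), type = c("Medication", "ADE"),
      start = c(0L, 15L), end = c(7L, 21L), text = c("Zalprex", "nausea"))
    if (extra) {
      ents <- dplyr::bind_rows(ents, tibble::tibble(
        id = "T3", type = "SSLIF", start = 35L, end = 41L, text = "tremor"))
    }
    ade_document("w", txt, ents)
  }
  c1 <- build_relation_candidates(mk(txt1, FALSE))
  c2 <- build_relation_candidates(mk(txt2, TRUE))
  c2 <- c2[c2$e1 == "T1" & c2$e2 == "T2", ]
  i1 <- adex:::re_prepare_instance(c1[1, ], tokenize_text(txt1), fit$vocab,
                                   fit$config)
  i2 <- adex:::re_prepare_instance(c2[1, ], tokenize_text(txt2), fit$vocab,
                                   fit$config)
  expect_identical(i1$dist, i2$dist)
  expect_identical(i1$count, i2$count)
  expect_equal(adex:::re_classify_instance(fit, i1),
               adex:::re_classify_instance(fit, i2))
})
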