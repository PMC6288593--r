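train_tiny <- function(mode, seed = 3L, epochs = 1L, lambda = 1e-3,
                       n_docs = 6L) {
  key <- paste("mtl", mode, seed, epochs, lambda, n_docs)
  cached(key, {
    corpus <- small_corpus(n_docs = n_docs, seed = 17L)
    train_multitask(corpus$train, mode = mode,
                    ner_config = fast_ner_cfg(epochs = epochs, seed = seed),
                    re_config = fast_re_cfg(epochs = epochs, seed = seed),
                    mtl_cfg = mtl_config(lambda_reg = lambda), seed = seed)
  })
}

test_that("hard sharing couples the tasks through the shared layer only", {
  model <- train_tiny("hard")
  params <- model$params
  expect_true(any(grepl("^share\\.lstm", names(params))))
  # zeroing the shared layer changes the NER output: sharing is real
  corpus <- small_corpus(n_docs = 2L, seed = 17L)
  prep <- adex:::ner_prepare_docs(corpus$train[1], vocab = model$ner$vocab)
  feat <- prep$sentences[[1]]
  emis <- function(p) {
    adex:::ad_tape_begin()
    e <- adex:::ner_emissions_node(p, model$ner$config, feat, train = FALSE,
                                   encoder = model$ner$encoder)$val
    adex:::ad_tape_end()
    e
  }
  p0 <- params
  for (nm in grep("^share\\.lstm", names(p0), value = TRUE)) {
    p0[[nm]][] <- 0
  }
  expect_false(isTRUE(all.equal(emis(params), emis(p0))))
})

test_that("an NER gradient step leaves RE-private parameters untouched", {
  model <- train_tiny("hard")
  params <- model$params
  corpus <- small_corpus(n_docs = 2L, seed = 17L)
  prep <- adex:::ner_prepare_docs(corpus$train[1], vocab = model$ner$vocab)
  adex:::ad_tape_begin()
  l <- adex:::ner_loss_node(params, model$ner$config, prep$sentences[[1]],
                            train = FALSE, encoder = model$ner$encoder)
  g <- adex:::ad_backward(l)
  adex:::ad_tape_end()
  # gradient partition: shared and NER-private groups present, RE absent
  expect_true(any(grepl("^share\\.lstm", names(g))))
  expect_true(any(grepl("^ner\\.", names(g))))
  expect_false(any(grepl("^re\\.", names(g))))
  st <- adex:::adam_new(lr = 1e-2)
  stepped <- adex:::adam_step(st, params, g)
  re_names <- grep("^re\\.", names(params), value = TRUE)
  expect_identical(stepped[re_names], params[re_names]) # bitwise unchanged
  sh <- grep("^share\\.lstm", names(params), value = TRUE)
  expect_false(identical(stepped[sh], params[sh]))
})

test_that("an RE gradient step leaves NER-private parameters untouched", {
  model <- train_tiny("hard")
  params <- model$params
  corpus <- small_corpus(n_docs = 2L, seed = 17L)
  prep <- adex:::re_prepare_docs(corpus$train, model$re$config,
                                 vocab = model$re$vocab)
  adex:::ad_tape_begin()
  l <- adex:::re_loss_node(params, model$re$config, prep$instances[[1]],
                           train = FALSE, encoder = model$re$encoder)
  g <- adex:::ad_backward(l)
  adex:::ad_tape_end()
  expect_true(any(grepl("^share\\.lstm", names(g))))
  expect_false(any(grepl("^ner\\.", names(g))))
  st <- adex:::adam_new(lr = 1e-2)
  stepped <- adex:::adam_step(st, params, g)
  ner_names <- grep("^ner\\.", names(params), value = TRUE)
  expect_identical(stepped[ner_names], params[ner_names])
})

test_that("the tying penalty has its closed forms", {
  expect_equal(regmtl_penalty(diag(3), diag(3), lambda = 5), 0)
  k <- 12L
  a <- matrix(rnorm(k), 3L, 4L)
  expect_equal(regmtl_penalty(a, a + 1, lambda = 1), k)
  expect_equal(regmtl_penalty(a, a + 1, lambda = 0.5), k / 2)
  expect_error(regmtl_penalty(a, diag(3), lambda = 1), "shape")
  # list form over parameter collections
  expect_equal(regmtl_penalty(list(a, diag(2)), list(a + 1, diag(2)), 1), k)
})

test_that("the penalty gradient pulls the tied layers together", {
  set.seed(55)
  params <- list("ner.p" = matrix(rnorm(6), 2L, 3L),
                 "re.p" = matrix(rnorm(6), 2L, 3L))
  dist <- function(p) sum((p[["ner.p"]] - p[["re.p"]])^2)
  d0 <- dist(params)
  st <- adex:::adam_new(lr = 5e-2)
  for (i in 1:50) {
    adex:::ad_tape_begin()
    pen <- adex:::ad_scale(adex:::ad_sum(adex:::ad_sq(adex:::ad_sub(
      adex:::ad_par(params, "ner.p"), adex:::ad_par(params, "re.p")))), 1)
    g <- adex:::ad_backward(pen)
    adex:::ad_tape_end()
    params <- adex:::adam_step(st, params, g)
  }
  expect_lt(dist(params), d0 / 10)
})

test_that("larger tying weights force the layer distance down", {
  dists <- vapply(c(0, 0.1, 3), function(lam) {
    m <- train_tiny("reg", seed = 7L, epochs = 2L, lambda = lam)
    nn <- adex:::reg_layer_names("ner")
    rn <- adex:::reg_layer_names("re")
    sum(vapply(seq_along(nn), function(i) {
      sum((m$params[[nn[i]]] - m$params[[rn[i]]])^2)
    }, 0))
  }, 0)
  expect_true(all(diff(dists) < 0)) # monotone decreasing over lambda
})

test_that("zeroed exchange maps reduce to the widened no-exchange baseline", {
  model <- train_tiny("learn")
  params <- model$params
  params[["learn.W5.re2ner"]][] <- 0
  params[["learn.W5.ner2re"]][] <- 0
  corpus <- small_corpus(n_docs = 2L, seed = 17L)
  doc <- corpus$train[[1]]
  toks <- tokenize_text(doc$text)
  sent <- adex:::split_sentences(toks)[[1]]
  feat <- adex:::ner_prepare_sentence(sent, model$ner$vocab)
  exch_dim <- ncol(model$params[["learn.W5.re2ner"]])
  # model output with W5 = 0
  adex:::ad_tape_begin()
  extra <- model$ner$exchanger(params, sent)
  e1 <- adex:::ner_emissions_node(params, model$ner$config, feat,
                                  train = FALSE, extra_row = extra)$val
  adex:::ad_tape_end()
  expect_true(all(extra$val == 0))
  # baseline: explicit zero exchange vector
  adex:::ad_tape_begin()
  zero <- adex:::ad_const(matrix(0, 1L, exch_dim))
  e2 <- adex:::ner_emissions_node(params, model$ner$config, feat,
                                  train = FALSE, extra_row = zero)$val
  adex:::ad_tape_end()
  expect_identical(e1, e2)
  # perturbing W5 changes the decoder output
  params2 <- params
  params2[["learn.W5.re2ner"]][] <- 0.3
  adex:::ad_tape_begin()
  extra3 <- model$ner$exchanger(params2, sent)
  e3 <- adex:::ner_emissions_node(params2, model$ner$config, feat,
                                  train = FALSE, extra_row = extra3)$val
  adex:::ad_tape_end()
  expect_false(isTRUE(all.equal(e1, e3)))
  # decoder input width contract
  expect_identical(nrow(model$params[["ner.out.W"]]),
                   model$ner$config$lstm_hidden + exch_dim)
})

test_that("invalid modes and empty corpora are rejected", {
  expect_error(train_multitask(list(), mode = "hard"), "empty")
  corpus <- small_corpus(n_docs = 2L, seed = 17L)
  expect_error(train_multitask(corpus$train, mode = "nonsense"))
  model <- train_tiny("hard")
  expect_error(hardmtl_forward(model, "segmentation", NULL), "unknown task")
})
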