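# Multi-task couplings of the entity recognizer and relation classifier.
#
# Three couplings are implemented next to the uncoupled pipeline baseline:
#
# * hard  - shared-private architecture: each task keeps a private
#   bidirectional recurrent layer and both feed a shared one (reached
#   through a small task-private linear adapter, since the two tasks'
#   token-feature widths differ); private and shared outputs are
#   concatenated before the task decoder. The shared layer receives
#   gradient from both tasks.
# * reg   - soft sharing by regularization: each task has two stacked
#   recurrent layers; an L2 penalty lambda * sum((p2_ner - p2_re)^2) ties
#   the second-layer parameters together (first layers differ in input
#   width, so only the second layers are comparable).
# * learn - task relation learning: each task's pooled hidden
#   representation is mapped through a linear exchange layer (one map per
#   direction) and concatenated into the other task's decoder input.
#
# Training alternates one NER mini-batch with one RE mini-batch, cycling
# the shorter loader. Every source of randomness is drawn from per-task
# streams, and the optimiser only steps parameters that received gradient,
# so (a) an NER step in hard mode leaves RE-private parameters bitwise
# unchanged, and (b) reg mode with lambda = 0 reproduces the pipeline
# trajectories exactly under identical seeds.

#' Configuration for multi-task training
#'
#' @param shared_input_dim Width of the task-private linear adapters feeding
#'   the shared recurrent layer (hard sharing).
#' @param shared_hidden Total bidirectional width of the shared layer.
#' @param exchange_dim Width of the exchange vectors (task relation
#'   learning).
#' @param lambda_reg L2 penalty weight tying the two second-layer parameter
#'   sets (soft sharing by regularization); `0` decouples the tasks.
#' @return A list of class `ade_mtl_config`.
#' @export
mtl_config <- function(shared_input_dim = 24L, shared_hidden = 32L,
                       exchange_dim = 16L, lambda_reg = 1e-3) {
  stopifnot(shared_input_dim >= 1L, shared_hidden >= 2L, exchange_dim >= 1L,
            lambda_reg >= 0)
  structure(list(shared_input_dim = as.integer(shared_input_dim),
                 shared_hidden = as.integer(shared_hidden),
                 exchange_dim = as.integer(exchange_dim),
                 lambda_reg = lambda_reg),
            class = "ade_mtl_config")
}

# Names of the second-layer recurrent parameters of one task.
reg_layer_names <- function(prefix) {
  as.vector(outer(c(".fw", ".bw"), c(".W", ".U", ".b"),
                  function(a, b) paste0(prefix, ".lstm2", a, b)))
}

#' L2 parameter-tying penalty
#'
#' `lambda * sum((p_ner - p_re)^2)` over all entries of the paired
#' parameter collections (matrices or lists of matrices with matching
#' shapes).
#'
#' @param p_ner,p_re A matrix, or list of matrices, of identical shapes.
#' @param lambda Penalty weight (>= 0).
#' @return Scalar penalty value.
#' @export
#' @examples
#' regmtl_penalty(diag(2), diag(2) + 1, lambda = 1) # 4 entries -> 4
regmtl_penalty <- function(p_ner, p_re, lambda) {
  if (is.matrix(p_ner)) p_ner <- list(p_ner)
  if (is.matrix(p_re)) p_re <- list(p_re)
  stopifnot(length(p_ner) == length(p_re))
  tot <- 0
  for (i in seq_along(p_ner)) {
    if (!identical(dim(p_ner[[i]]), dim(p_re[[i]]))) {
      stop("shape mismatch in parameter pair ", i)
    }
    tot <- tot + sum((p_ner[[i]] - p_re[[i]])^2)
  }
  lambda * tot
}

# Tape node version of the penalty, over named parameter pairs.
reg_penalty_node <- function(params, lambda) {
  nn <- reg_layer_names("ner")
  rn <- reg_layer_names("re")
  acc <- NULL
  for (i in seq_along(nn)) {
    d <- ad_sum(ad_sq(ad_sub(ad_par(params, nn[i]), ad_par(params, rn[i]))))
    acc <- if (is.null(acc)) d else ad_add(acc, d)
  }
  ad_scale(acc, lambda)
}

## ---- mode-specific encoders and exchange hooks ---------------------------

hard_ner_encoder <- function(mcfg) {
  function(params, cfg, x) {
    priv <- ner_default_encoder(params, cfg, x)
    sh <- bilstm_run(params, "share.lstm",
                     ad_mm(x, ad_par(params, "ner.adapt")),
                     mcfg$shared_hidden)
    ad_hcat(list(priv, sh))
  }
}

hard_re_encoder <- function(mcfg) {
  function(params, cfg, x) {
    priv <- re_default_encoder(params, cfg, x)
    sh <- bilstm_run(params, "share.lstm",
                     ad_mm(x, ad_par(params, "re.adapt")),
                     mcfg$shared_hidden)
    ad_hcat(list(priv, sh))
  }
}

# Exchange vector for an NER sentence: run the RE-side encoder over the
# same tokens (neutral positions), attention-pool, map through W5.
learn_exchange_for_ner <- function(params, re_cfg, re_feat) {
  x <- ad_hcat(list(
    ad_rows(ad_par(params, "re.word.emb"), re_feat$widx),
    ad_rows(ad_par(params, "re.pos.emb"), re_feat$pidx),
    ad_rows(ad_par(params, "re.d1.emb"), re_feat$d1),
    ad_rows(ad_par(params, "re.d2.emb"), re_feat$d2)
  ))
  h <- re_default_encoder(params, re_cfg, x)
  att <- attention_run(params, "re.attn", h)
  ad_mm(att$context, ad_par(params, "learn.W5.re2ner"))
}

# Exchange vector for an RE instance: run the NER-side encoder over the
# window tokens, mean-pool, map through W5.
learn_exchange_for_re <- function(params, ner_cfg, ner_feat) {
  x <- ner_features_node(params, ner_cfg, ner_feat, train = FALSE)
  h <- ner_default_encoder(params, ner_cfg, x)
  n <- nrow(h$val)
  pooled <- ad_mm(ad_const(matrix(1 / n, 1L, n)), h)
  ad_mm(pooled, ad_par(params, "learn.W5.ner2re"))
}

# Neutral RE-side features for a plain sentence (no target entities:
# position channels sit at distance 0).
re_neutral_features <- function(sentence, re_vocab, re_cfg) {
  list(widx = vocab_index(re_vocab$word, tolower(sentence$text)),
       pidx = vocab_index(re_vocab$pos, sentence$pos),
       d1 = rep(re_cfg$max_position + 1L, nrow(sentence)),
       d2 = rep(re_cfg$max_position + 1L, nrow(sentence)))
}

## ---- coupling forward probes ---------------------------------------------

#' Forward pass of the hard-sharing model for one task
#'
#' Runs an input through the task-private and shared recurrent layers and
#' the task decoder. For `task = "ner"` pass a prepared sentence feature
#' list and obtain the emission matrix; for `task = "re"` pass a prepared
#' instance and obtain the 8-class probability vector.
#'
#' @param model A trained `ade_mtl` with `mode == "hard"`.
#' @param task `"ner"` or `"re"`.
#' @param instance A prepared feature list (see [ner_fit()]/[re_fit()]
#'   internals via `model$ner$vocab`).
#' @return Emission matrix (`ner`) or probability vector (`re`).
#' @export
hardmtl_forward <- function(model, task, instance) {
  stopifnot(inherits(model, "ade_mtl"), model$mode == "hard")
  if (!task %in% c("ner", "re")) stop("unknown task: ", task)
  if (task == "ner") {
    ad_tape_begin()
    e <- ner_emissions_node(model$params, model$ner$config, instance,
                            train = FALSE, encoder = model$ner$encoder)
    out <- e$val
    ad_tape_end()
    out
  } else {
    re_classify_instance(model$re, instance)
  }
}

#' Forward pass of the task-relation-learning model for one task
#'
#' Each task's decoder consumes the concatenation of its own hidden
#' representation and the exchange vector computed from the counterpart
#' encoder. For `task = "ner"` the instance is a list
#' `list(feat = <prepared sentence>, sentence = <token tibble>)`; for
#' `task = "re"` it is a prepared instance list carrying `ner_feat`.
#'
#' @inheritParams hardmtl_forward
#' @return Emission matrix (`ner`) or probability vector (`re`).
#' @export
learnmtl_forward <- function(model, task, instance) {
  stopifnot(inherits(model, "ade_mtl"), model$mode == "learn")
  if (!task %in% c("ner", "re")) stop("unknown task: ", task)
  if (task == "ner") {
    ad_tape_begin()
    extra <- model$ner$exchanger(model$params, instance$sentence)
    e <- ner_emissions_node(model$params, model$ner$config, instance$feat,
                            train = FALSE, extra_row = extra)
    out <- e$val
    ad_tape_end()
    out
  } else {
    ad_tape_begin()
    extra <- learn_exchange_for_re(model$params, model$ner$config,
                                   instance$ner_feat)
    z <- re_logits_node(model$params, model$re$config, instance,
                        train = FALSE, exchange = extra)
    p <- ad_softmax(z)$val
    ad_tape_end()
    as.vector(p)
  }
}

## ---- joint training ------------------------------------------------------

#' Train the two submodels under a multi-task coupling
#'
#' Prepares both tasks' data from the same tokenisation, initialises all
#' parameter groups from per-task seeds, and alternates one NER mini-batch
#' with one RE mini-batch (cycling the shorter loader) for up to
#' `max(ner_config$epochs, re_config$epochs)` epochs. Each task stops
#' updating once its mean epoch loss falls under its `stop_loss`.
#'
#' @param docs Training documents.
#' @param mode `"pipeline"` (no coupling), `"hard"`, `"reg"`, or `"learn"`.
#' @param ner_config An [ner_config()]; in `reg` mode its `lstm_layers` is
#'   forced to 2 (the penalty ties the second layers).
#' @param re_config An [re_config()]; same note for `reg`.
#' @param mtl_cfg An [mtl_config()].
#' @param seed Master seed; per-task streams are derived from it.
#' @return An `ade_mtl` object: trained `ner` and `re` submodels (usable
#'   with [predict_entities()] and [extract_relations()]), the joint
#'   parameter list, the `mode`, and a per-epoch `log` tibble with both
#'   task losses and the penalty.
#' @export
train_multitask <- function(docs, mode = c("pipeline", "hard", "reg", "learn"),
                            ner_config = ade_small_ner_config(),
                            re_config = ade_small_re_config(),
                            mtl_cfg = mtl_config(), seed = 1L) {
  mode <- match.arg(mode)
  docs <- as_doc_list(docs)
  if (length(docs) == 0L) stop("empty training corpus")
  if (mode == "reg") {
    ner_config$lstm_layers <- 2L
    re_config$lstm_layers <- 2L
    if (ner_config$lstm_hidden != re_config$lstm_hidden) {
      stop("reg mode requires equal lstm_hidden in both tasks")
    }
  }
  token_tables <- lapply(docs, function(d) tokenize_text(d$text))

  ner_prep <- ner_prepare_docs(docs)
  re_prep <- re_prepare_docs(docs, re_config, token_tables = token_tables)

  # learn mode: counterpart features for every training item
  if (mode == "learn") {
    k <- 1L
    for (di in seq_along(docs)) {
      sents <- split_sentences(token_tables[[di]])
      for (s in sents) {
        ner_prep$sentences[[k]]$re_feat <-
          re_neutral_features(s, re_prep$vocab, re_config)
        k <- k + 1L
      }
    }
    cand <- re_prep$candidates
    for (i in seq_along(re_prep$instances)) {
      di <- match(cand$doc_id[i], vapply(docs, `[[`, "", "doc_id"))
      toks <- token_tables[[di]]
      win <- cand$win_from[i]:cand$win_to[i]
      re_prep$instances[[i]]$ner_feat <-
        ner_prepare_sentence(toks[win, ], ner_prep$vocab)
    }
  }

  ner_stream <- rng_stream(derive_seed(seed, "ner"))
  re_stream <- rng_stream(derive_seed(seed, "re"))
  mtl_stream <- rng_stream(derive_seed(seed, "mtl"))

  ner_enc_out <- switch(mode,
    hard = ner_config$lstm_hidden + mtl_cfg$shared_hidden,
    learn = ner_config$lstm_hidden + mtl_cfg$exchange_dim,
    ner_config$lstm_hidden)
  re_enc_out <- switch(mode,
    hard = re_config$lstm_hidden + mtl_cfg$shared_hidden,
    re_config$lstm_hidden)
  re_extra <- if (mode == "learn") mtl_cfg$exchange_dim else 0L

  params <- with_stream(ner_stream,
                        ner_init_params(ner_config, ner_prep$vocab,
                                        enc_out_dim = ner_enc_out))
  params <- c(params,
              with_stream(re_stream,
                          re_init_params(re_config, re_prep$vocab,
                                         enc_out_dim = if (mode == "hard")
                                           re_enc_out else NULL,
                                         extra_out_dim = re_extra)))
  ner_in <- ner_config$word_dim + ner_config$capital_dim +
    ner_config$pos_dim + ner_config$char_cnn_filters
  re_in <- re_config$word_dim + re_config$pos_dim +
    2L * re_config$position_dim
  if (mode == "hard") {
    params <- c(params, with_stream(mtl_stream, {
      p <- list()
      p[["ner.adapt"]] <- glorot(ner_in, mtl_cfg$shared_input_dim)
      p[["re.adapt"]] <- glorot(re_in, mtl_cfg$shared_input_dim)
      c(p, bilstm_init(mtl_cfg$shared_input_dim, mtl_cfg$shared_hidden,
                       "share.lstm"))
    }))
  }
  if (mode == "learn") {
    params <- c(params, with_stream(mtl_stream, {
      list("learn.W5.ner2re" = glorot(ner_config$lstm_hidden,
                                      mtl_cfg$exchange_dim),
           "learn.W5.re2ner" = glorot(re_config$lstm_hidden,
                                      mtl_cfg$exchange_dim))
    }))
  }

  ner_encoder <- if (mode == "hard") hard_ner_encoder(mtl_cfg) else NULL
  re_encoder <- if (mode == "hard") hard_re_encoder(mtl_cfg) else NULL

  ner_loss <- function(params, feat) {
    extra <- if (mode == "learn") {
      learn_exchange_for_ner(params, re_config, feat$re_feat)
    } else NULL
    ner_loss_node(params, ner_config, feat, train = TRUE,
                  encoder = ner_encoder, extra_row = extra)
  }
  re_loss <- function(params, inst) {
    extra <- if (mode == "learn") {
      learn_exchange_for_re(params, ner_config, inst$ner_feat)
    } else NULL
    re_loss_node(params, re_config, inst, train = TRUE, encoder = re_encoder,
                 exchange = extra)
  }

  st <- adam_new(lr = ner_config$learning_rate)
  penalty_on <- mode == "reg" && mtl_cfg$lambda_reg > 0
  n_sent <- length(ner_prep$sentences)
  n_inst <- length(re_prep$instances)
  if (n_inst == 0L) stop("no relation candidates in the training corpus")
  epochs <- max(ner_config$epochs, re_config$epochs)
  log_rows <- list()
  ner_active <- TRUE
  re_active <- TRUE

  run_batch <- function(items, loss_fn, stream, lr) {
    ad_tape_begin()
    loss <- NULL
    with_stream(stream, {
      for (it in items) {
        l <- loss_fn(params, it)
        loss <- if (is.null(loss)) l else ad_add(loss, l)
      }
    })
    loss <- ad_scale(loss, 1 / length(items))
    pen <- 0
    if (penalty_on) {
      pn <- reg_penalty_node(params, mtl_cfg$lambda_reg)
      pen <- pn$val[1L]
      loss <- ad_add(loss, pn)
    }
    v <- loss$val[1L] - pen
    grads <- ad_backward(loss)
    ad_tape_end()
    st$lr <- lr
    params <<- adam_step(st, params, grads)
    c(v, pen)
  }

  for (ep in seq_len(epochs)) {
    ner_batches <- if (ner_active) {
      split_batches(with_stream(ner_stream, sample.int(n_sent)),
                    ner_config$batch_size)
    } else list()
    re_batches <- if (re_active) {
      split_batches(with_stream(re_stream, sample.int(n_inst)),
                    re_config$batch_size)
    } else list()
    nb <- max(length(ner_batches), length(re_batches))
    ner_tot <- 0; ner_n <- 0L; re_tot <- 0; re_n <- 0L
    pen_tot <- 0; pen_n <- 0L
    for (bi in seq_len(nb)) {
      # 1:1 alternation; the shorter loader is cycled
      if (length(ner_batches) > 0) {
        b <- ner_batches[[((bi - 1L) %% length(ner_batches)) + 1L]]
        r <- run_batch(ner_prep$sentences[b], ner_loss, ner_stream,
                       ner_config$learning_rate)
        ner_tot <- ner_tot + r[1L] * length(b); ner_n <- ner_n + length(b)
        pen_tot <- pen_tot + r[2L]; pen_n <- pen_n + 1L
      }
      if (length(re_batches) > 0) {
        b <- re_batches[[((bi - 1L) %% length(re_batches)) + 1L]]
        r <- run_batch(re_prep$instances[b], re_loss, re_stream,
                       re_config$learning_rate)
        re_tot <- re_tot + r[1L] * length(b); re_n <- re_n + length(b)
        pen_tot <- pen_tot + r[2L]; pen_n <- pen_n + 1L
      }
    }
    row <- tibble::tibble(
      epoch = ep,
      ner_loss = if (ner_n > 0) ner_tot / ner_n else NA_real_,
      re_loss = if (re_n > 0) re_tot / re_n else NA_real_,
      penalty = if (pen_n > 0) pen_tot / pen_n else 0)
    log_rows[[ep]] <- row
    if (ner_active && !is.null(ner_config$stop_loss) &&
          !is.na(row$ner_loss) && row$ner_loss < ner_config$stop_loss) {
      ner_active <- FALSE
    }
    if (re_active && !is.null(re_config$stop_loss) && !is.na(row$re_loss) &&
          row$re_loss < re_config$stop_loss) {
      re_active <- FALSE
    }
    if (!ner_active && !re_active) break
  }
  log <- dplyr::bind_rows(log_rows)

  re_vocab <- re_prep$vocab
  ner_vocab <- ner_prep$vocab
  ner_exchanger <- NULL
  re_exchanger <- NULL
  if (mode == "learn") {
    ner_exchanger <- function(params, sentence) {
      learn_exchange_for_ner(params, re_config,
                             re_neutral_features(sentence, re_vocab,
                                                 re_config))
    }
    re_exchanger <- function(params, cand, tokens) {
      win <- cand$win_from:cand$win_to
      nf <- ner_prepare_sentence(tokens[win, ], ner_vocab)
      learn_exchange_for_re(params, ner_config, nf)
    }
  }
  ner_model <- structure(
    list(params = params, vocab = ner_vocab, config = ner_config,
         log = log, trained = TRUE, encoder = ner_encoder,
         exchanger = ner_exchanger),
    class = "ade_ner")
  re_model <- structure(
    list(params = params, vocab = re_vocab, config = re_config,
         log = log, trained = TRUE, encoder = re_encoder,
         exchanger = re_exchanger),
    class = "ade_re")
  structure(list(mode = mode, params = params, ner = ner_model,
                 re = re_model, mtl_cfg = mtl_cfg, log = log, seed = seed),
            class = "ade_mtl")
}

split_batches <- function(ord, size) {
  if (length(ord) == 0L) return(list())
  split(ord, ceiling(seq_along(ord) / size))
}

#' @export
print.ade_mtl <- function(x, ...) {
  cat("<ade_mtl> mode=", x$mode, ", ", nrow(x$log), " epochs trained\n",
      sep = "")
  invisible(x)
}
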