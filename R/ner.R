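# Sequence labeler for the nine entity types: per-token features (word,
# initial-capital flag, POS tag, character representation from a
# convolutional layer) are concatenated, encoded by a bidirectional LSTM,
# projected to per-label emission scores, and decoded by a linear-chain CRF.

#' Configuration for the entity recognizer
#'
#' Defaults are conventional for this architecture family: 100-d word
#' embeddings, 30-d character embeddings convolved into 50 filters of width
#' 3, 20-d POS and 5-d capitalisation embeddings, 200 total recurrent units
#' (100 per direction), dropout 0.5 on the input features, Adam at 1e-3.
#'
#' @param word_dim,char_dim,char_cnn_filters,char_cnn_kernel,pos_dim,capital_dim
#'   Feature embedding sizes.
#' @param lstm_hidden Total bidirectional hidden width (split across the two
#'   directions). @param lstm_layers Number of stacked bidirectional layers.
#' @param dropout Input dropout probability in `[0, 1)`.
#' @param learning_rate,batch_size,epochs Optimisation settings (Adam).
#' @param seed Integer seed controlling initialisation, shuffling, dropout.
#' @param stop_loss Early-stopping threshold on the mean epoch loss
#'   (`NULL` = run all epochs).
#' @param constrain_decoding Apply the hard BMES structural-transition mask
#'   at decode time (transition scores to structurally impossible label
#'   bigrams are otherwise learned, not masked).
#' @return A list of class `ade_ner_config`.
#' @export
ner_config <- function(word_dim = 100L, char_dim = 30L, char_cnn_filters = 50L,
                       char_cnn_kernel = 3L, pos_dim = 20L, capital_dim = 5L,
                       lstm_hidden = 200L, lstm_layers = 1L, dropout = 0.5,
                       learning_rate = 1e-3, batch_size = 8L, epochs = 20L,
                       seed = 1L, stop_loss = NULL, constrain_decoding = FALSE) {
  cfg <- list(word_dim = word_dim, char_dim = char_dim,
              char_cnn_filters = char_cnn_filters,
              char_cnn_kernel = char_cnn_kernel, pos_dim = pos_dim,
              capital_dim = capital_dim, lstm_hidden = lstm_hidden,
              lstm_layers = lstm_layers, dropout = dropout,
              learning_rate = learning_rate, batch_size = batch_size,
              epochs = epochs, seed = seed, stop_loss = stop_loss,
              constrain_decoding = constrain_decoding)
  stopifnot(all(vapply(cfg[1:7], function(x) x >= 1L, TRUE)),
            dropout >= 0, dropout < 1)
  structure(cfg, class = "ade_ner_config")
}

#' Small training profile for the entity recognizer
#'
#' A reduced-width configuration sized to the bundled synthetic corpora
#' (small closed vocabularies, short template sentences), where full-width
#' embeddings are unnecessary; used throughout the package's own
#' experiments.
#'
#' @param ... Overrides passed to [ner_config()].
#' @return An `ade_ner_config`.
#' @export
ade_small_ner_config <- function(...) {
  defaults <- list(word_dim = 24L, char_dim = 10L, char_cnn_filters = 12L,
                   char_cnn_kernel = 3L, pos_dim = 8L, capital_dim = 4L,
                   lstm_hidden = 32L, dropout = 0.15, learning_rate = 8e-3,
                   batch_size = 8L, epochs = 18L, stop_loss = 0.04)
  do.call(ner_config, utils::modifyList(defaults, list(...)))
}

# Build vocabularies from tokenised training documents.
ner_vocab_build <- function(token_tables) {
  all_tok <- dplyr::bind_rows(token_tables)
  list(
    word = vocab_build(tolower(all_tok$text)),
    char = vocab_build(unlist(strsplit(all_tok$text, "", fixed = TRUE))),
    pos = vocab_build(all_tok$pos),
    labels = bmes_labels()
  )
}

# Precompute integer features for one sentence.
ner_prepare_sentence <- function(sentence, vocab, labels = NULL) {
  list(
    widx = vocab_index(vocab$word, tolower(sentence$text)),
    pidx = vocab_index(vocab$pos, sentence$pos),
    capidx = ifelse(sentence$initial_capital, 2L, 1L),
    chidx = lapply(sentence$text, char_indices, char_vocab = vocab$char),
    tokens = sentence$text,
    yidx = if (is.null(labels)) NULL else match(labels, vocab$labels)
  )
}

ner_init_params <- function(cfg, vocab, enc_prefix = "ner", enc_out_dim = NULL) {
  L <- length(vocab$labels)
  in_dim <- cfg$word_dim + cfg$capital_dim + cfg$pos_dim + cfg$char_cnn_filters
  p <- list()
  p[["ner.word.emb"]] <- embed_init(length(vocab$word), cfg$word_dim)
  p[["ner.cap.emb"]] <- embed_init(2L, cfg$capital_dim)
  p[["ner.pos.emb"]] <- embed_init(length(vocab$pos), cfg$pos_dim)
  p <- c(p, char_cnn_init(length(vocab$char), cfg$char_dim,
                          cfg$char_cnn_filters, cfg$char_cnn_kernel,
                          prefix = "ner.char"))
  d <- in_dim
  for (l in seq_len(cfg$lstm_layers)) {
    p <- c(p, bilstm_init(d, cfg$lstm_hidden, paste0(enc_prefix, ".lstm", l)))
    d <- cfg$lstm_hidden
  }
  out_dim <- enc_out_dim %||% cfg$lstm_hidden
  p[["ner.out.W"]] <- glorot(out_dim, L)
  p[["ner.out.b"]] <- matrix(0, 1L, L)
  p[["ner.trans"]] <- matrix(stats::rnorm((L + 2L)^2, 0, 0.01), L + 2L, L + 2L)
  p
}

# Per-token feature matrix node (n x in_dim); char representations are
# cached per distinct token text within a tape.
ner_features_node <- function(params, cfg, feat, train = FALSE) {
  chars <- lapply(seq_along(feat$chidx), function(i) {
    char_cnn_run(params, "ner.char", feat$chidx[[i]], cfg$char_cnn_kernel,
                 pad_idx = 1L, cache_key = paste0("c:", feat$tokens[[i]]))
  })
  x <- ad_hcat(list(
    ad_rows(ad_par(params, "ner.word.emb"), feat$widx),
    ad_rows(ad_par(params, "ner.cap.emb"), feat$capidx),
    ad_rows(ad_par(params, "ner.pos.emb"), feat$pidx),
    ad_vcat(chars)
  ))
  if (train && cfg$dropout > 0) x <- ad_dropout(x, cfg$dropout) else x
}

# Default stacked-BiLSTM encoder under a prefix.
ner_default_encoder <- function(params, cfg, x, prefix = "ner") {
  h <- x
  for (l in seq_len(cfg$lstm_layers)) {
    h <- bilstm_run(params, paste0(prefix, ".lstm", l), h, cfg$lstm_hidden)
  }
  h
}

# Emission scores node (n x 37) for one prepared sentence. `extra_row`
# (1 x k node), when given, is broadcast down the tokens and concatenated
# to the encoder output before the projection (task-relation exchange).
ner_emissions_node <- function(params, cfg, feat, train = FALSE,
                               encoder = NULL, extra_row = NULL) {
  x <- ner_features_node(params, cfg, feat, train = train)
  h <- if (is.null(encoder)) ner_default_encoder(params, cfg, x) else
    encoder(params, cfg, x)
  if (!is.null(extra_row)) {
    n <- nrow(h$val)
    h <- ad_hcat(list(h, ad_mm(ad_const(matrix(1, n, 1L)), extra_row)))
  }
  ad_badd_row(ad_mm(h, ad_par(params, "ner.out.W")),
              ad_par(params, "ner.out.b"))
}

# Tape loss node for one sentence (CRF negative log-likelihood).
ner_loss_node <- function(params, cfg, feat, train = TRUE, encoder = NULL,
                          extra_row = NULL) {
  e <- ner_emissions_node(params, cfg, feat, train = train, encoder = encoder,
                          extra_row = extra_row)
  crf_nll_node(e, ad_par(params, "ner.trans"), feat$yidx)
}

# Tokenise + encode labels for a document set; returns list with tokens and
# prepared per-sentence feature lists.
ner_prepare_docs <- function(docs, vocab = NULL) {
  docs <- as_doc_list(docs)
  token_tables <- lapply(docs, function(d) tokenize_text(d$text))
  if (is.null(vocab)) vocab <- ner_vocab_build(token_tables)
  sentences <- list()
  snapped <- 0L
  for (k in seq_along(docs)) {
    sents <- split_sentences(token_tables[[k]])
    labs <- lapply(sents, encode_bmes, entities = docs[[k]]$entities)
    snapped <- snapped + sum(vapply(labs, function(x) attr(x, "snapped"), 0L))
    for (s in seq_along(sents)) {
      sentences[[length(sentences) + 1L]] <-
        ner_prepare_sentence(sents[[s]], vocab, labels = labs[[s]])
    }
  }
  list(vocab = vocab, sentences = sentences, tokens = token_tables,
       snapped = snapped)
}

#' Train the entity recognizer
#'
#' Mini-batch Adam on the CRF negative log-likelihood. All randomness
#' (initialisation, shuffling, dropout) is drawn from one stream derived
#' from `config$seed`, so a fixed seed gives a bit-reproducible model.
#'
#' @param docs Training documents (list of `ade_document`).
#' @param config An [ner_config()].
#' @param pretrained Optional embeddings from [read_word_embeddings()];
#'   matching vocabulary rows are copied in and frozen (not tuned) by
#'   default.
#' @param tune_pretrained Tune pretrained embedding rows (default `FALSE`).
#' @return An object of class `ade_ner` with elements `params`, `vocab`,
#'   `config`, and a per-epoch training `log` tibble.
#' @export
ner_fit <- function(docs, config = ner_config(), pretrained = NULL,
                    tune_pretrained = FALSE) {
  prep <- ner_prepare_docs(docs)
  stream <- rng_stream(derive_seed(config$seed, "ner"))
  params <- with_stream(stream, ner_init_params(config, prep$vocab))
  frozen <- character(0)
  if (!is.null(pretrained)) {
    hit <- match(prep$vocab$word, pretrained$words)
    rows <- which(!is.na(hit))
    if (length(rows) > 0) {
      d <- min(ncol(pretrained$vectors), config$word_dim)
      params[["ner.word.emb"]][rows, seq_len(d)] <-
        pretrained$vectors[hit[rows], seq_len(d)]
    }
    if (!tune_pretrained) frozen <- "ner.word.emb"
  }
  st <- adam_new(lr = config$learning_rate)
  log <- ner_train_loop(params, config, prep$sentences, st, stream, frozen)
  structure(list(params = log$params, vocab = prep$vocab, config = config,
                 log = log$log, snapped_spans = prep$snapped, trained = TRUE),
            class = "ade_ner")
}

ner_train_loop <- function(params, cfg, sentences, st, stream, frozen) {
  ns <- length(sentences)
  rows <- list()
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_stream(stream, sample.int(ns))
    total <- 0
    i <- 1L
    while (i <= ns) {
      batch <- ord[i:min(ns, i + cfg$batch_size - 1L)]
      ad_tape_begin()
      loss <- NULL
      with_stream(stream, {
        for (b in batch) {
          l <- ner_loss_node(params, cfg, sentences[[b]], train = TRUE)
          loss <- if (is.null(loss)) l else ad_add(loss, l)
        }
      })
      loss <- ad_scale(loss, 1 / length(batch))
      total <- total + loss$val[1L] * length(batch)
      grads <- ad_backward(loss)
      ad_tape_end()
      grads[frozen] <- NULL
      params <- adam_step(st, params, grads)
      i <- i + cfg$batch_size
    }
    rows[[ep]] <- tibble::tibble(epoch = ep, loss = total / ns)
    if (!is.null(cfg$stop_loss) && rows[[ep]]$loss < cfg$stop_loss) break
  }
  list(params = params, log = dplyr::bind_rows(rows))
}

#' Predict entities for a document
#'
#' Runs the trained recognizer sentence by sentence (Viterbi decoding,
#' ties broken toward the lowest label index), converts the BMES output
#' back to character-offset spans, and returns a copy of the document
#' carrying the predicted entities (ids `T1`, `T2`, ... in text order) and
#' no relations.
#'
#' @param model A trained `ade_ner`.
#' @param doc An `ade_document`.
#' @param tokens Optional precomputed token table for `doc`.
#' @return An `ade_document` with predicted entities.
#' @export
predict_entities <- function(model, doc, tokens = NULL) {
  stopifnot(inherits(model, "ade_ner"))
  if (!isTRUE(model$trained)) stop("model has not been trained")
  if (is.null(tokens)) tokens <- tokenize_text(doc$text)
  cfg <- model$config
  mask <- if (isTRUE(cfg$constrain_decoding)) bmes_transition_mask() else NULL
  ents <- list()
  for (sent in split_sentences(tokens)) {
    feat <- ner_prepare_sentence(sent, model$vocab)
    ad_tape_begin()
    extra <- if (is.null(model$exchanger)) NULL else
      model$exchanger(model$params, sent)
    e <- ner_emissions_node(model$params, cfg, feat, train = FALSE,
                            encoder = model$encoder, extra_row = extra)
    emis <- e$val
    ad_tape_end()
    dec <- viterbi_decode(emis, model$params[["ner.trans"]], mask = mask)
    labs <- model$vocab$labels[dec$labels]
    sp <- decode_bmes(labs, sent, text = doc$text)
    if (nrow(sp) > 0) ents[[length(ents) + 1L]] <- sp
  }
  ents <- if (length(ents)) dplyr::bind_rows(ents) else {
    e <- empty_entities(); e$id <- NULL; e
  }
  ents <- dplyr::arrange(ents, .data$start)
  ents <- dplyr::mutate(ents, id = paste0("T", dplyr::row_number()),
                        .before = 1L)
  set_annotations(doc, entities = ents, relations = empty_relations())
}
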