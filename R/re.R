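# Relation classifier: a candidate's context window is encoded per token
# from word, POS, and two position embeddings (signed distances to each
# target entity; character features are deliberately absent here), run
# through a bidirectional LSTM, pooled by additive attention into a context
# vector, concatenated with entity-pair side features (entity words, entity
# types, bucketed token distance, bucketed entity count between), and
# classified by a softmax over the seven relation types plus "None".

#' Relation label set
#'
#' @return Character vector of the 8 classes: the seven relation types plus
#'   `"None"`.
#' @export
relation_labels <- function() {
  c(ade_relation_types()$type, "None")
}

#' Configuration for the relation classifier
#'
#' @param word_dim,pos_dim,position_dim Token feature embedding sizes (two
#'   position channels, one per target entity).
#' @param max_position Positions are clipped at `+/-max_position`.
#' @param lstm_hidden Total bidirectional hidden width.
#' @param lstm_layers Stacked bidirectional layers.
#' @param attention_dim Width of the attention projection.
#' @param type_dim,dist_dim,count_dim Side-feature embedding sizes (entity
#'   types; bucketed token distance; bucketed entity count between).
#' @param dropout Input dropout in `[0, 1)`.
#' @param learning_rate,batch_size,epochs Optimisation settings (Adam).
#' @param seed Integer seed.
#' @param max_sentence_gap Candidate generation: maximum sentence distance.
#' @param neg_keep Fraction of `"None"` training candidates kept (1 = all).
#' @param stop_loss Early-stopping threshold on mean epoch loss.
#' @return A list of class `ade_re_config`.
#' @export
re_config <- function(word_dim = 100L, pos_dim = 20L, position_dim = 20L,
                      max_position = 30L, lstm_hidden = 200L, lstm_layers = 1L,
                      attention_dim = 100L, type_dim = 10L, dist_dim = 10L,
                      count_dim = 10L, dropout = 0.5, learning_rate = 1e-3,
                      batch_size = 16L, epochs = 20L, seed = 1L,
                      max_sentence_gap = 3L, neg_keep = 1.0,
                      stop_loss = NULL) {
  stopifnot(max_position >= 1L, dropout >= 0, dropout < 1,
            neg_keep > 0, neg_keep <= 1)
  structure(list(word_dim = word_dim, pos_dim = pos_dim,
                 position_dim = position_dim, max_position = max_position,
                 lstm_hidden = lstm_hidden, lstm_layers = lstm_layers,
                 attention_dim = attention_dim, type_dim = type_dim,
                 dist_dim = dist_dim, count_dim = count_dim,
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs, seed = seed,
                 max_sentence_gap = max_sentence_gap, neg_keep = neg_keep,
                 stop_loss = stop_loss),
            class = "ade_re_config")
}

#' Small training profile for the relation classifier
#'
#' @param ... Overrides passed to [re_config()].
#' @return An `ade_re_config`.
#' @export
ade_small_re_config <- function(...) {
  defaults <- list(word_dim = 24L, pos_dim = 8L, position_dim = 8L,
                   max_position = 20L, lstm_hidden = 32L,
                   attention_dim = 24L, type_dim = 6L, dist_dim = 6L,
                   count_dim = 6L, dropout = 0.15, learning_rate = 8e-3,
                   batch_size = 16L, epochs = 18L, stop_loss = 0.03)
  do.call(re_config, utils::modifyList(defaults, list(...)))
}

re_vocab_build <- function(token_tables) {
  all_tok <- dplyr::bind_rows(token_tables)
  list(word = vocab_build(tolower(all_tok$text)),
       pos = vocab_build(all_tok$pos),
       types = ade_entity_types(),
       labels = relation_labels())
}

# Integer features for one candidate (window indices etc.).
re_prepare_instance <- function(cand, tokens, vocab, cfg) {
  win <- cand$win_from:cand$win_to
  pos <- compute_positions(cand, max_position = cfg$max_position)
  list(
    widx = vocab_index(vocab$word, tolower(tokens$text[win])),
    pidx = vocab_index(vocab$pos, tokens$pos[win]),
    # signed positions shifted into 1..(2*max_position+1)
    d1 = pos$positions1 + cfg$max_position + 1L,
    d2 = pos$positions2 + cfg$max_position + 1L,
    e1_widx = vocab_index(vocab$word,
                          tolower(tokens$text[cand$e1_from:cand$e1_to])),
    e2_widx = vocab_index(vocab$word,
                          tolower(tokens$text[cand$e2_from:cand$e2_to])),
    t1 = match(cand$e1_type, vocab$types),
    t2 = match(cand$e2_type, vocab$types),
    dist = distance_bucket(cand$token_distance) + 1L,
    count = distance_bucket(cand$entity_count_between) + 1L,
    yidx = match(cand$label, vocab$labels)
  )
}

re_init_params <- function(cfg, vocab, enc_prefix = "re", enc_out_dim = NULL,
                           extra_out_dim = 0L) {
  npos <- 2L * cfg$max_position + 1L
  p <- list()
  p[["re.word.emb"]] <- embed_init(length(vocab$word), cfg$word_dim)
  p[["re.pos.emb"]] <- embed_init(length(vocab$pos), cfg$pos_dim)
  p[["re.d1.emb"]] <- embed_init(npos, cfg$position_dim)
  p[["re.d2.emb"]] <- embed_init(npos, cfg$position_dim)
  p[["re.type.emb"]] <- embed_init(length(vocab$types), cfg$type_dim)
  p[["re.dist.emb"]] <- embed_init(6L, cfg$dist_dim)
  p[["re.count.emb"]] <- embed_init(6L, cfg$count_dim)
  in_dim <- cfg$word_dim + cfg$pos_dim + 2L * cfg$position_dim
  d <- in_dim
  for (l in seq_len(cfg$lstm_layers)) {
    p <- c(p, bilstm_init(d, cfg$lstm_hidden, paste0(enc_prefix, ".lstm", l)))
    d <- cfg$lstm_hidden
  }
  p <- c(p, attention_init(enc_out_dim %||% cfg$lstm_hidden,
                           cfg$attention_dim, "re.attn"))
  side_dim <- 2L * cfg$word_dim + 2L * cfg$type_dim + cfg$dist_dim +
    cfg$count_dim
  out_in <- (enc_out_dim %||% cfg$lstm_hidden) + side_dim + extra_out_dim
  p[["re.out.W"]] <- glorot(out_in, length(vocab$labels))
  p[["re.out.b"]] <- matrix(0, 1L, length(vocab$labels))
  p
}

re_features_node <- function(params, cfg, inst, train = FALSE) {
  x <- ad_hcat(list(
    ad_rows(ad_par(params, "re.word.emb"), inst$widx),
    ad_rows(ad_par(params, "re.pos.emb"), inst$pidx),
    ad_rows(ad_par(params, "re.d1.emb"), inst$d1),
    ad_rows(ad_par(params, "re.d2.emb"), inst$d2)
  ))
  if (train && cfg$dropout > 0) ad_dropout(x, cfg$dropout) else x
}

re_default_encoder <- function(params, cfg, x, prefix = "re") {
  h <- x
  for (l in seq_len(cfg$lstm_layers)) {
    h <- bilstm_run(params, paste0(prefix, ".lstm", l), h, cfg$lstm_hidden)
  }
  h
}

# Mean word embedding of a (possibly multi-word) entity: order-free.
re_entity_word_node <- function(params, widx) {
  m <- ad_rows(ad_par(params, "re.word.emb"), widx)
  ad_mm(ad_const(matrix(1 / length(widx), 1L, length(widx))), m)
}

re_side_node <- function(params, inst) {
  te <- ad_par(params, "re.type.emb")
  ad_hcat(list(
    re_entity_word_node(params, inst$e1_widx),
    re_entity_word_node(params, inst$e2_widx),
    ad_rows(te, inst$t1),
    ad_rows(te, inst$t2),
    ad_rows(ad_par(params, "re.dist.emb"), inst$dist),
    ad_rows(ad_par(params, "re.count.emb"), inst$count)
  ))
}

# Logits node (1 x 8) for one instance; `exchange` optionally appends an
# extra vector (task-relation learning) before the output layer.
re_logits_node <- function(params, cfg, inst, train = FALSE, encoder = NULL,
                           exchange = NULL) {
  x <- re_features_node(params, cfg, inst, train = train)
  h <- if (is.null(encoder)) re_default_encoder(params, cfg, x) else
    encoder(params, cfg, x)
  att <- attention_run(params, "re.attn", h)
  pieces <- list(att$context, re_side_node(params, inst))
  if (!is.null(exchange)) pieces <- c(pieces, list(exchange))
  ad_badd_row(ad_mm(ad_hcat(pieces), ad_par(params, "re.out.W")),
              ad_par(params, "re.out.b"))
}

# Cross-entropy loss node for one instance.
re_loss_node <- function(params, cfg, inst, train = TRUE, encoder = NULL,
                         exchange = NULL) {
  z <- re_logits_node(params, cfg, inst, train = train, encoder = encoder,
                      exchange = exchange)
  ad_sub(ad_lse(z), ad_entry(z, 1L, inst$yidx))
}

# Candidate instances for a document set. Entities may be gold or predicted;
# labels come from gold relations (all "None" when none exist).
re_prepare_docs <- function(docs, cfg, vocab = NULL, token_tables = NULL) {
  docs <- as_doc_list(docs)
  if (is.null(token_tables)) {
    token_tables <- lapply(docs, function(d) tokenize_text(d$text))
  }
  if (is.null(vocab)) vocab <- re_vocab_build(token_tables)
  insts <- list()
  cands <- list()
  for (k in seq_along(docs)) {
    cand <- build_relation_candidates(docs[[k]], tokens = token_tables[[k]],
                                      max_sentence_gap = cfg$max_sentence_gap)
    if (nrow(cand) == 0L) next
    cands[[length(cands) + 1L]] <- cand
    for (i in seq_len(nrow(cand))) {
      insts[[length(insts) + 1L]] <-
        re_prepare_instance(cand[i, ], token_tables[[k]], vocab, cfg)
    }
  }
  list(vocab = vocab, instances = insts,
       candidates = if (length(cands)) dplyr::bind_rows(cands) else
         empty_candidates(),
       tokens = token_tables)
}

#' Train the relation classifier
#'
#' Mini-batch Adam on the cross-entropy over the 8 classes (7 relation
#' types plus `"None"`). Negative candidates can be down-sampled with
#' `config$neg_keep`.
#'
#' @param docs Training documents with gold entities and relations.
#' @param config An [re_config()].
#' @return An object of class `ade_re` with `params`, `vocab`, `config`,
#'   and a per-epoch `log` tibble.
#' @export
re_fit <- function(docs, config = re_config()) {
  prep <- re_prepare_docs(docs, config)
  stream <- rng_stream(derive_seed(config$seed, "re"))
  insts <- prep$instances
  if (config$neg_keep < 1) {
    is_neg <- vapply(insts, function(x) {
      x$yidx == length(relation_labels())
    }, TRUE)
    keep <- with_stream(stream, stats::runif(length(insts)) <= config$neg_keep)
    insts <- insts[!is_neg | keep]
  }
  params <- with_stream(stream, re_init_params(config, prep$vocab))
  st <- adam_new(lr = config$learning_rate)
  log <- re_train_loop(params, config, insts, st, stream)
  structure(list(params = log$params, vocab = prep$vocab, config = config,
                 log = log$log, trained = TRUE),
            class = "ade_re")
}

re_train_loop <- function(params, cfg, insts, st, stream) {
  ni <- length(insts)
  if (ni == 0L) stop("no relation candidates in the training corpus")
  rows <- list()
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_stream(stream, sample.int(ni))
    total <- 0
    i <- 1L
    while (i <= ni) {
      batch <- ord[i:min(ni, i + cfg$batch_size - 1L)]
      ad_tape_begin()
      loss <- NULL
      with_stream(stream, {
        for (b in batch) {
          l <- re_loss_node(params, cfg, insts[[b]], train = TRUE)
          loss <- if (is.null(loss)) l else ad_add(loss, l)
        }
      })
      loss <- ad_scale(loss, 1 / length(batch))
      total <- total + loss$val[1L] * length(batch)
      grads <- ad_backward(loss)
      ad_tape_end()
      params <- adam_step(st, params, grads)
      i <- i + cfg$batch_size
    }
    rows[[ep]] <- tibble::tibble(epoch = ep, loss = total / ni)
    if (!is.null(cfg$stop_loss) && rows[[ep]]$loss < cfg$stop_loss) break
  }
  list(params = params, log = dplyr::bind_rows(rows))
}

# Class probabilities (1 x 8) for one prepared instance, without dropout.
# `cand`/`tokens` feed the optional exchange hook of task-relation models.
re_classify_instance <- function(model, inst, cand = NULL, tokens = NULL) {
  ad_tape_begin()
  extra <- if (is.null(model$exchanger)) NULL else
    model$exchanger(model$params, cand, tokens)
  z <- re_logits_node(model$params, model$config, inst, train = FALSE,
                      encoder = model$encoder, exchange = extra)
  p <- ad_softmax(z)$val
  ad_tape_end()
  as.vector(p)
}

#' Extract relations from a document
#'
#' Builds type-compatible candidates over the document's entities (gold or
#' predicted), classifies each, and keeps non-`"None"` argmax predictions
#' as relations with canonical argument order. An exact probability tie is
#' resolved conservatively to `"None"`.
#'
#' @param model A trained `ade_re`.
#' @param doc An `ade_document` whose `entities` are populated.
#' @param tokens Optional precomputed token table.
#' @return The document with predicted `relations` (ids `R1`, `R2`, ...).
#' @export
extract_relations <- function(model, doc, tokens = NULL) {
  stopifnot(inherits(model, "ade_re"))
  if (!isTRUE(model$trained)) stop("model has not been trained")
  if (is.null(tokens)) tokens <- tokenize_text(doc$text)
  cfg <- model$config
  cand <- build_relation_candidates(doc, tokens = tokens,
                                    max_sentence_gap = cfg$max_sentence_gap)
  if (nrow(cand) == 0L) {
    return(set_annotations(doc, relations = empty_relations()))
  }
  labels <- model$vocab$labels
  sig <- ade_relation_types()
  rels <- list()
  for (i in seq_len(nrow(cand))) {
    inst <- re_prepare_instance(cand[i, ], tokens, model$vocab, cfg)
    p <- re_classify_instance(model, inst, cand = cand[i, ], tokens = tokens)
    k <- which.max(p)
    if (sum(p == p[k]) > 1L) next # tie -> "None"
    lab <- labels[k]
    if (lab == "None") next
    # a pair admits exactly one schema-compatible relation type; any other
    # predicted label cannot be emitted without violating the schema
    if (lab != relation_for_pair(cand$e1_type[i], cand$e2_type[i])) next
    srow <- sig[sig$type == lab, ]
    a1 <- if (cand$e1_type[i] == srow$arg1_type) cand$e1[i] else cand$e2[i]
    a2 <- if (cand$e1_type[i] == srow$arg1_type) cand$e2[i] else cand$e1[i]
    rels[[length(rels) + 1L]] <- tibble::tibble(type = lab, arg1 = a1,
                                                arg2 = a2)
  }
  rels <- if (length(rels)) dplyr::bind_rows(rels) else empty_relations()[, -1L]
  rels <- dplyr::mutate(rels, id = paste0("R", dplyr::row_number()),
                        .before = 1L)
  set_annotations(doc, relations = rels)
}
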