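# End-to-end orchestration: generate (or load) a corpus, train the
# requested model(s), predict on the test split, and evaluate entities,
# relations on gold entities, and relations end-to-end (entity errors
# propagating). Every run embeds a provenance block (config hash, seed,
# package version) in its report.

#' Configuration for an end-to-end run
#'
#' @param gen A [gen_config()] for the synthetic corpus (ignored when
#'   `corpus_dir` is given).
#' @param ner,re,mtl Submodel and coupling configurations.
#' @param mode One of `"pipeline"`, `"hard"`, `"reg"`, `"learn"`, `"all"`.
#' @param seed Master seed for training (corpus generation uses
#'   `gen$seed`).
#' @param replicates Number of training replicates; replicate `k` uses
#'   `seed + k - 1` and reported metrics are per-replicate rows.
#' @param corpus_dir Optional directory of standoff files with `train/` and
#'   `test/` subdirectories, used instead of the generator.
#' @return A list of class `ade_run_config`.
#' @export
run_config <- function(gen = gen_config(), ner = ade_small_ner_config(),
                       re = ade_small_re_config(), mtl = mtl_config(),
                       mode = "pipeline", seed = 1L, replicates = 1L,
                       corpus_dir = NULL) {
  stopifnot(mode %in% c("pipeline", "hard", "reg", "learn", "all"),
            replicates >= 1L)
  structure(list(gen = gen, ner = ner, re = re, mtl = mtl, mode = mode,
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 corpus_dir = corpus_dir),
            class = "ade_run_config")
}

# FNV-1a hash of a string, hex; used for config provenance.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA)
  h <- 2166136261 %% 2147483647
  for (k in utf8ToInt(as.character(s))) {
    h <- (bitwXor(as.integer(h), k) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Predict test documents end-to-end and on gold entities.
predict_corpus <- function(model, docs) {
  docs <- as_doc_list(docs)
  token_tables <- lapply(docs, function(d) tokenize_text(d$text))
  e2e <- vector("list", length(docs))
  gold_ent <- vector("list", length(docs))
  for (i in seq_along(docs)) {
    pe <- predict_entities(model$ner, docs[[i]], tokens = token_tables[[i]])
    e2e[[i]] <- extract_relations(model$re, pe, tokens = token_tables[[i]])
    ge <- set_annotations(docs[[i]], relations = empty_relations())
    gold_ent[[i]] <- extract_relations(model$re, ge,
                                       tokens = token_tables[[i]])
  }
  list(end_to_end = e2e, gold_entities = gold_ent)
}

# Metric rows for one trained model on a test set.
evaluate_model <- function(model, test_docs, mode, replicate = 1L) {
  pred <- predict_corpus(model, test_docs)
  ner_m <- micro_prf(match_entities(test_docs, pred$end_to_end))
  re_gold <- micro_prf(match_relations(test_docs, pred$gold_entities))
  re_e2e <- micro_prf(match_relations(test_docs, pred$end_to_end))
  dplyr::bind_rows(
    dplyr::mutate(ner_m, mode = mode, task = "ner", replicate = replicate,
                  .before = 1L),
    dplyr::mutate(re_gold, mode = mode, task = "re_gold",
                  replicate = replicate, .before = 1L),
    dplyr::mutate(re_e2e, mode = mode, task = "re_end_to_end",
                  replicate = replicate, .before = 1L))
}

#' Run the full pipeline: generate, train, predict, evaluate
#'
#' @param cfg An [run_config()].
#' @return A list of class `ade_report`: `provenance` (config hash, seed,
#'   package version), `metrics` (tibble with micro-averaged P/R/F1 per
#'   mode for entity recognition, relation extraction on gold entities,
#'   and end-to-end relation extraction), `stats` (corpus statistics), and
#'   `logs` (per-mode training logs).
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "ade_run_config"))
  if (is.null(cfg$corpus_dir)) {
    corpus <- generate_corpus(cfg$gen)
    train_docs <- corpus$train
    test_docs <- corpus$test
  } else {
    train_docs <- read_standoff_dir(file.path(cfg$corpus_dir, "train"),
                                    split = "train")
    test_docs <- read_standoff_dir(file.path(cfg$corpus_dir, "test"),
                                   split = "test")
  }
  modes <- if (cfg$mode == "all") c("pipeline", "hard", "reg", "learn") else
    cfg$mode
  metrics <- list()
  logs <- list()
  for (mode in modes) {
    for (k in seq_len(cfg$replicates)) {
      model <- train_multitask(train_docs, mode = mode,
                               ner_config = cfg$ner, re_config = cfg$re,
                               mtl_cfg = cfg$mtl, seed = cfg$seed + k - 1L)
      metrics[[length(metrics) + 1L]] <-
        evaluate_model(model, test_docs, mode, replicate = k)
      logs[[paste(mode, k, sep = "_")]] <- model$log
    }
  }
  structure(list(
    provenance = list(config_hash = config_hash(unclass_deep(cfg)),
                      seed = cfg$seed,
                      package_version =
                        as.character(utils::packageVersion("adex"))),
    metrics = dplyr::bind_rows(metrics),
    stats = corpus_stats(train_docs),
    logs = logs), class = "ade_report")
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Serialise a run report to JSON
#'
#' @param report An `ade_report` from [run_pipeline()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  out <- list(provenance = report$provenance,
              metrics = report$metrics,
              entity_counts = report$stats$entities,
              relation_counts = report$stats$relations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.ade_report <- function(x, ...) {
  cat("<ade_report> seed ", x$provenance$seed, ", config ",
      x$provenance$config_hash, "\n", sep = "")
  m <- dplyr::mutate(x$metrics,
                     dplyr::across(c("precision", "recall", "f1"),
                                   ~ round(100 * .x, 1)))
  print(as.data.frame(m[, c("mode", "task", "precision", "recall", "f1")]))
  invisible(x)
}

## ---- checkpoints ---------------------------------------------------------

#' Save a trained submodel checkpoint
#'
#' Parameters, vocabularies and configuration are serialised together as
#' JSON (plain text). Models holding mode-specific encoders (from
#' [train_multitask()] with a coupling) should be retrained rather than
#' checkpointed; this covers the plain pipeline submodels.
#'
#' @param model An `ade_ner` or `ade_re`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("ade_ner", "ade_re")))
  if (!is.null(model$encoder) || !is.null(model$exchanger)) {
    stop("coupled models cannot be checkpointed; retrain with the same seed")
  }
  obj <- list(kind = class(model)[1L],
              config = unclass_deep(model$config),
              vocab = model$vocab,
              params = lapply(model$params, function(m) {
                list(dim = dim(m), data = as.vector(m))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a submodel checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The restored `ade_ner` or `ade_re`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    matrix(p$data, p$dim[1L], p$dim[2L])
  })
  cfg <- obj$config
  cls <- obj$kind
  cfg_class <- if (cls == "ade_ner") "ade_ner_config" else "ade_re_config"
  vocab <- lapply(obj$vocab, function(v) v)
  structure(list(params = params,
                 vocab = vocab,
                 config = structure(cfg, class = cfg_class),
                 log = NULL, trained = TRUE),
            class = cls)
}
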