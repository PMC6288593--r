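# Document container: raw text plus entity and relation tables. Offsets are
# 0-based, half-open [start, end), the dominant standoff convention.

empty_entities <- function() {
  tibble::tibble(id = character(), type = character(),
                 start = integer(), end = integer(), text = character())
}

empty_relations <- function() {
  tibble::tibble(id = character(), type = character(),
                 arg1 = character(), arg2 = character())
}

#' Construct an annotated document
#'
#' @param doc_id Document identifier.
#' @param text Full document text (one string).
#' @param entities Tibble with columns `id`, `type`, `start`, `end`, `text`;
#'   character offsets are 0-based, half-open.
#' @param relations Tibble with columns `id`, `type`, `arg1`, `arg2` where
#'   `arg1`/`arg2` are entity ids.
#' @param split One of `"train"`, `"test"`, `"none"`.
#' @return An object of class `ade_document`.
#' @export
ade_document <- function(doc_id, text,
                         entities = empty_entities(),
                         relations = empty_relations(),
                         split = "none") {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L,
            split %in% c("train", "test", "none"))
  entities <- tibble::as_tibble(entities)
  relations <- tibble::as_tibble(relations)
  if (nrow(entities) > 0) {
    entities$start <- as.integer(entities$start)
    entities$end <- as.integer(entities$end)
    if (anyDuplicated(entities$id)) stop("duplicate entity ids in ", doc_id)
    if (any(entities$start < 0L | entities$start >= entities$end |
              entities$end > nchar(text))) {
      stop("entity offsets out of range in ", doc_id)
    }
    got <- substr_many(text, entities$start, entities$end)
    bad <- which(got != entities$text)
    if (length(bad) > 0) {
      stop("entity text does not match document substring in ", doc_id,
           " (entity ", entities$id[bad[1L]], ")")
    }
  }
  if (nrow(relations) > 0) {
    if (anyDuplicated(relations$id)) stop("duplicate relation ids in ", doc_id)
    if (any(relations$arg1 == relations$arg2)) {
      stop("relation with identical arguments in ", doc_id)
    }
    missing <- setdiff(c(relations$arg1, relations$arg2), entities$id)
    if (length(missing) > 0) {
      stop("relation references missing entity '", missing[1L], "' in ", doc_id)
    }
  }
  structure(list(doc_id = doc_id, text = text, entities = entities,
                 relations = relations, split = split),
            class = "ade_document")
}

# Vectorised substring on 0-based half-open offsets.
substr_many <- function(text, start, end) {
  substring(text, start + 1L, end)
}

#' @export
print.ade_document <- function(x, ...) {
  cat("<ade_document> ", x$doc_id, " (", nchar(x$text), " chars, ",
      nrow(x$entities), " entities, ", nrow(x$relations), " relations, split=",
      x$split, ")\n", sep = "")
  invisible(x)
}

#' Collect entity annotations of a corpus into one table
#'
#' @param docs A list of `ade_document` objects (or a single document).
#' @return A tibble of entities with a leading `doc_id` column.
#' @export
corpus_entities <- function(docs) {
  docs <- as_doc_list(docs)
  purrr::map_dfr(docs, function(d) {
    if (nrow(d$entities) == 0) return(NULL)
    dplyr::mutate(d$entities, doc_id = d$doc_id, .before = 1L)
  })
}

#' Collect relation annotations of a corpus into one table
#'
#' @inheritParams corpus_entities
#' @return A tibble of relations with a leading `doc_id` column.
#' @export
corpus_relations <- function(docs) {
  docs <- as_doc_list(docs)
  purrr::map_dfr(docs, function(d) {
    if (nrow(d$relations) == 0) return(NULL)
    dplyr::mutate(d$relations, doc_id = d$doc_id, .before = 1L)
  })
}

as_doc_list <- function(docs) {
  if (inherits(docs, "ade_document")) list(docs) else docs
}

# Replace predicted annotations, revalidating invariants.
set_annotations <- function(doc, entities = NULL, relations = NULL) {
  ade_document(doc$doc_id, doc$text,
               entities = entities %||% doc$entities,
               relations = relations %||% doc$relations,
               split = doc$split)
}
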