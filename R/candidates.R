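# Relation-candidate generation. A candidate is an ordered entity pair
# (earlier entity in text first) whose types match one of the seven relation
# signatures and whose sentence distance does not exceed `max_sentence_gap`
# (inter-sentence relations are real in clinical text, but long-distance
# ones are increasingly hard; the gap is the exposed trade-off). The context
# window runs from the first token of the earlier sentence to the last token
# of the later sentence.

# Token-index span [from, to] covering an entity's character span.
entity_token_span <- function(tokens, start, end) {
  idx <- which(tokens$start < end & tokens$end > start)
  if (length(idx) == 0L) return(c(NA_integer_, NA_integer_))
  c(min(idx), max(idx))
}

#' Generate relation candidates for a document
#'
#' @param doc An `ade_document` with entities (gold or predicted).
#' @param tokens Token table from [tokenize_text()]; computed from
#'   `doc$text` when omitted.
#' @param max_sentence_gap Maximum sentence distance between the two
#'   entities (0 = same sentence). Default 3.
#' @return A tibble with one row per candidate: entity ids/types, token
#'   spans (`e1_from` .. `e2_to`), window token span (`win_from`,
#'   `win_to`), `sent_gap`, `token_distance`, `entity_count_between`, and
#'   `label` (the gold relation type when one links the pair, otherwise
#'   `"None"`).
#' @export
build_relation_candidates <- function(doc, tokens = NULL, max_sentence_gap = 3L) {
  stopifnot(inherits(doc, "ade_document"))
  if (is.null(tokens)) tokens <- tokenize_text(doc$text)
  ents <- doc$entities
  if (nrow(ents) < 2L || nrow(tokens) == 0L) return(empty_candidates())
  spans <- t(vapply(seq_len(nrow(ents)), function(i) {
    entity_token_span(tokens, ents$start[i], ents$end[i])
  }, integer(2L)))
  ok <- !is.na(spans[, 1L])
  ents <- ents[ok, , drop = FALSE]
  spans <- spans[ok, , drop = FALSE]
  if (nrow(ents) < 2L) return(empty_candidates())
  sent_of <- tokens$sentence_index
  sent_bounds <- tapply(seq_len(nrow(tokens)), sent_of, range)
  gold_key <- character(0)
  gold_type <- character(0)
  if (nrow(doc$relations) > 0) {
    gold_key <- paste(doc$relations$arg1, doc$relations$arg2)
    gold_type <- doc$relations$type
  }
  rows <- list()
  ord <- order(ents$start, ents$end)
  ents <- ents[ord, , drop = FALSE]
  spans <- spans[ord, , drop = FALSE]
  ne <- nrow(ents)
  for (i in seq_len(ne - 1L)) {
    for (j in (i + 1L):ne) {
      rtype <- relation_for_pair(ents$type[i], ents$type[j])
      if (is.na(rtype)) next
      s1 <- sent_of[spans[i, 1L]]
      s2 <- sent_of[spans[j, 2L]]
      gap <- abs(s2 - s1)
      if (gap > max_sentence_gap) next
      # gold relations may store the pair in either order
      kk <- which(gold_key == paste(ents$id[i], ents$id[j]) |
                    gold_key == paste(ents$id[j], ents$id[i]))
      label <- if (length(kk) > 0L) gold_type[kk[1L]] else "None"
      win_from <- sent_bounds[[as.character(min(s1, s2))]][1L]
      win_to <- sent_bounds[[as.character(max(s1, s2))]][2L]
      between <- sum(ents$start >= ents$end[i] & ents$end <= ents$start[j])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        doc_id = doc$doc_id,
        e1 = ents$id[i], e2 = ents$id[j],
        e1_type = ents$type[i], e2_type = ents$type[j],
        e1_text = ents$text[i], e2_text = ents$text[j],
        e1_from = spans[i, 1L], e1_to = spans[i, 2L],
        e2_from = spans[j, 1L], e2_to = spans[j, 2L],
        win_from = win_from, win_to = win_to,
        sent_gap = gap,
        token_distance = max(0L, spans[j, 1L] - spans[i, 2L] - 1L),
        entity_count_between = between,
        label = label)
    }
  }
  if (length(rows) == 0L) return(empty_candidates())
  dplyr::bind_rows(rows)
}

empty_candidates <- function() {
  tibble::tibble(doc_id = character(), e1 = character(), e2 = character(),
                 e1_type = character(), e2_type = character(),
                 e1_text = character(), e2_text = character(),
                 e1_from = integer(), e1_to = integer(),
                 e2_from = integer(), e2_to = integer(),
                 win_from = integer(), win_to = integer(),
                 sent_gap = integer(), token_distance = integer(),
                 entity_count_between = integer(), label = character())
}

#' Signed token distances to the two target entities
#'
#' For each token of a candidate's window, the signed distance to the
#' nearest boundary of each target entity: negative before the entity, 0
#' inside it, positive after, clipped at `+/-max_position`.
#'
#' @param cand One row of the candidate table.
#' @param max_position Clipping bound (>= 1).
#' @return A list with integer vectors `positions1` and `positions2`, one
#'   entry per window token.
#' @export
compute_positions <- function(cand, max_position = 30L) {
  idx <- cand$win_from:cand$win_to
  rel <- function(from, to) {
    d <- ifelse(idx < from, idx - from, ifelse(idx > to, idx - to, 0L))
    pmax(-max_position, pmin(max_position, d))
  }
  list(positions1 = rel(cand$e1_from, cand$e1_to),
       positions2 = rel(cand$e2_from, cand$e2_to))
}

# Bucketed distance feature: {0, 1, 2, 3-5, 6-10, >10} -> 0..5.
distance_bucket <- function(d) {
  ifelse(d <= 2L, d, ifelse(d <= 5L, 3L, ifelse(d <= 10L, 4L, 5L)))
}
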