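# BMES-with-type label coding. Spans are coded per sentence as
# B_t M_t ... E_t (multi-token) or S_t (single token); all other tokens are
# O. The label vocabulary therefore has 4 x 9 + 1 = 37 symbols.

#' BMES label vocabulary
#'
#' @return Character vector of the 37 labels: `O` first, then
#'   `{B,M,E,S}_<type>` for each of the nine entity types.
#' @export
bmes_labels <- function() {
  types <- ade_entity_types()
  c("O", as.vector(t(outer(c("B", "M", "E", "S"), types, paste, sep = "_"))))
}

#' Encode entity spans as a BMES label sequence
#'
#' Labels each token of one sentence according to the entities overlapping
#' it. Entity spans that do not align with token boundaries are snapped
#' outward to the smallest covering token span; the number of snapped spans
#' is reported in the `snapped` attribute. Overlapping entities within the
#' sentence are an error.
#'
#' @param sentence A per-sentence token tibble from [tokenize_text()].
#' @param entities Entity tibble (document-level offsets).
#' @return Character vector of labels, one per token, with attribute
#'   `snapped` (count of boundary-snapped spans).
#' @export
encode_bmes <- function(sentence, entities) {
  n <- nrow(sentence)
  labels <- rep("O", n)
  snapped <- 0L
  if (nrow(entities) == 0) return(structure(labels, snapped = snapped))
  # entities overlapping this sentence's character range
  s0 <- min(sentence$start); s1 <- max(sentence$end)
  ents <- entities[entities$start < s1 & entities$end > s0, , drop = FALSE]
  if (nrow(ents) == 0) return(structure(labels, snapped = snapped))
  covered <- rep(NA_character_, n)
  ord <- order(ents$start)
  ents <- ents[ord, , drop = FALSE]
  for (i in seq_len(nrow(ents))) {
    e <- ents[i, ]
    idx <- which(sentence$start < e$end & sentence$end > e$start)
    if (length(idx) == 0L) next
    if (sentence$start[idx[1L]] != e$start ||
          sentence$end[idx[length(idx)]] != e$end) {
      snapped <- snapped + 1L
    }
    clash <- idx[!is.na(covered[idx])]
    if (length(clash) > 0L) {
      stop("overlapping entities ", covered[clash[1L]], " and ", e$id,
           " at token '", sentence$text[clash[1L]], "'")
    }
    covered[idx] <- e$id
    if (length(idx) == 1L) {
      labels[idx] <- paste0("S_", e$type)
    } else {
      labels[idx[1L]] <- paste0("B_", e$type)
      labels[idx[length(idx)]] <- paste0("E_", e$type)
      mid <- idx[-c(1L, length(idx))]
      if (length(mid) > 0L) labels[mid] <- paste0("M_", e$type)
    }
  }
  structure(labels, snapped = snapped)
}

#' Decode a BMES label sequence back into entity spans
#'
#' Maximal well-formed `B (M)* E` runs and `S` labels become entities.
#' Ill-formed output is repaired deterministically, left to right: an `M` or
#' `E` with no open run of the same type becomes `O`; an open run
#' interrupted before its `E` (by `O`, a type switch, a new `B`, or the end
#' of the sentence) is emitted as an entity covering the tokens seen so far
#' (so a lone `B` yields a single-token entity).
#'
#' @param labels Character vector of BMES labels, one per token.
#' @param sentence The matching per-sentence token tibble.
#' @param text Document text used to fill the entity `text` column; when
#'   `NULL`, token texts are joined by single spaces.
#' @return Entity tibble (without ids) with 0-based half-open character
#'   offsets.
#' @export
decode_bmes <- function(labels, sentence, text = NULL) {
  stopifnot(length(labels) == nrow(sentence))
  spans <- list()
  open_type <- NULL
  open_start <- NA_integer_
  open_last <- NA_integer_
  emit <- function(from, to, type) {
    spans[[length(spans) + 1L]] <<- list(from = from, to = to, type = type)
  }
  close_open <- function() {
    if (!is.null(open_type)) emit(open_start, open_last, open_type)
    open_type <<- NULL
  }
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    if (lab == "O") { close_open(); next }
    tag <- substr(lab, 1L, 1L)
    type <- substr(lab, 3L, nchar(lab))
    if (tag == "S") {
      close_open(); emit(i, i, type)
    } else if (tag == "B") {
      close_open(); open_type <- type; open_start <- i; open_last <- i
    } else if (is.null(open_type) || open_type != type) {
      close_open() # orphan M/E -> O
    } else if (tag == "M") {
      open_last <- i
    } else { # E closing the open run
      open_last <- i; close_open()
    }
  }
  close_open()
  if (length(spans) == 0L) {
    out <- empty_entities()
    out$id <- NULL
    return(out)
  }
  from <- vapply(spans, `[[`, 0L, "from")
  to <- vapply(spans, `[[`, 0L, "to")
  type <- vapply(spans, `[[`, "", "type")
  start <- sentence$start[from]
  end <- sentence$end[to]
  surface <- if (is.null(text)) {
    vapply(seq_along(from), function(k) {
      paste(sentence$text[from[k]:to[k]], collapse = " ")
    }, "")
  } else {
    substr_many(text, start, end)
  }
  tibble::tibble(type = type, start = start, end = end, text = surface)
}

# Encode all sentences of a document; returns list of label vectors.
encode_document_bmes <- function(tokens, entities) {
  lapply(split_sentences(tokens), encode_bmes, entities = entities)
}
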