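# Micro-averaged evaluation with exact span matching: a predicted entity is
# a true positive iff an unmatched gold entity has the same document, start,
# end and type; a predicted relation additionally requires both argument
# spans (and their types) to match exactly, so in end-to-end scoring entity
# errors propagate into relation errors. Matching is multiset matching on
# keys: each gold annotation is consumed at most once.

count_by_key <- function(keys, types) {
  tb <- tibble::tibble(key = keys, type = types)
  dplyr::summarise(dplyr::group_by(tb, .data$type, .data$key),
                   n = dplyr::n(), .groups = "drop")
}

match_counts <- function(gold_keys, gold_types, pred_keys, pred_types) {
  all_types <- sort(unique(c(gold_types, pred_types)))
  g <- count_by_key(gold_keys, gold_types)
  p <- count_by_key(pred_keys, pred_types)
  j <- dplyr::full_join(g, p, by = c("type", "key"),
                        suffix = c("_gold", "_pred"))
  j$n_gold[is.na(j$n_gold)] <- 0L
  j$n_pred[is.na(j$n_pred)] <- 0L
  j$tpk <- pmin(j$n_gold, j$n_pred)
  out <- dplyr::summarise(dplyr::group_by(j, .data$type),
                          tp = sum(.data$tpk),
                          fp = sum(.data$n_pred - .data$tpk),
                          fn = sum(.data$n_gold - .data$tpk),
                          .groups = "drop")
  missing <- setdiff(all_types, out$type)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(type = missing, tp = 0L,
                                                fp = 0L, fn = 0L))
  }
  dplyr::arrange(out, .data$type)
}

#' Match predicted against gold entities
#'
#' Exact matching: a prediction counts as a true positive iff some not yet
#' matched gold entity in the same document has identical span and type.
#'
#' @param gold,pred Lists of `ade_document` (same document set; matched by
#'   `doc_id`).
#' @return A tibble of per-type counts `type`, `tp`, `fp`, `fn`.
#' @export
match_entities <- function(gold, pred) {
  ge <- corpus_entities(gold)
  pe <- corpus_entities(pred)
  key <- function(e) paste(e$doc_id, e$start, e$end, e$type)
  match_counts(if (nrow(ge)) key(ge) else character(0),
               if (nrow(ge)) ge$type else character(0),
               if (nrow(pe)) key(pe) else character(0),
               if (nrow(pe)) pe$type else character(0))
}

# Relations with arguments resolved to spans, in canonical signature order.
resolved_relations <- function(docs) {
  docs <- as_doc_list(docs)
  purrr::map_dfr(docs, function(d) {
    if (nrow(d$relations) == 0) return(NULL)
    ents <- d$entities
    ri <- d$relations
    a1 <- match(ri$arg1, ents$id)
    a2 <- match(ri$arg2, ents$id)
    if (anyNA(a1) || anyNA(a2)) {
      stop("dangling relation argument in ", d$doc_id)
    }
    sig <- ade_relation_types()
    want1 <- sig$arg1_type[match(ri$type, sig$type)]
    swap <- !is.na(want1) & ents$type[a1] != want1 & ents$type[a2] == want1
    t1 <- ifelse(swap, a2, a1)
    t2 <- ifelse(swap, a1, a2)
    tibble::tibble(
      doc_id = d$doc_id, type = ri$type,
      key = paste(d$doc_id, ri$type,
                  ents$start[t1], ents$end[t1], ents$type[t1],
                  ents$start[t2], ents$end[t2], ents$type[t2]))
  })
}

#' Match predicted against gold relations
#'
#' A predicted relation is a true positive iff an unmatched gold relation
#' has the same type and both argument entities match exactly by span and
#' type. When the predictions' entities come from the recognition stage
#' (end-to-end evaluation), entity errors propagate here.
#'
#' @inheritParams match_entities
#' @return A tibble of per-type counts `type`, `tp`, `fp`, `fn`.
#' @export
match_relations <- function(gold, pred) {
  gr <- resolved_relations(gold)
  pr <- resolved_relations(pred)
  match_counts(if (!is.null(gr) && nrow(gr)) gr$key else character(0),
               if (!is.null(gr) && nrow(gr)) gr$type else character(0),
               if (!is.null(pr) && nrow(pr)) pr$key else character(0),
               if (!is.null(pr) && nrow(pr)) pr$type else character(0))
}

#' Micro-averaged precision, recall and F1
#'
#' Sums counts over all rows (types) first, then applies
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`, with the `0/0 = 0`
#' convention throughout. Values are proportions in `[0, 1]`.
#'
#' @param counts A tibble with columns `tp`, `fp`, `fn` (one or more rows).
#' @return A one-row tibble `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
#' @examples
#' micro_prf(tibble::tibble(tp = 3, fp = 1, fn = 2))
micro_prf <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

# Per-type P/R/F1 rows plus a micro-averaged "ALL" row.
prf_table <- function(counts) {
  rows <- dplyr::bind_rows(lapply(seq_len(nrow(counts)), function(i) {
    dplyr::mutate(micro_prf(counts[i, ]), type = counts$type[i], .before = 1L)
  }))
  dplyr::bind_rows(dplyr::mutate(micro_prf(counts), type = "ALL",
                                 .before = 1L), rows)
}

#' Evaluate entity and relation extraction
#'
#' Computes micro-averaged and per-type precision/recall/F1 for entities
#' and for relations, under exact span matching. Pass predictions whose
#' entities came from the recognizer to obtain end-to-end relation scores.
#'
#' @inheritParams match_entities
#' @return A tibble with columns `task` (`"entity"`/`"relation"`), `type`
#'   (`"ALL"` for the micro-average, else the type), `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`; class `ade_evaluation`.
#' @export
evaluate_extraction <- function(gold, pred) {
  ent <- dplyr::mutate(prf_table(match_entities(gold, pred)),
                       task = "entity", .before = 1L)
  rel <- dplyr::mutate(prf_table(match_relations(gold, pred)),
                       task = "relation", .before = 1L)
  out <- dplyr::bind_rows(ent, rel)
  class(out) <- c("ade_evaluation", class(out))
  out
}
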