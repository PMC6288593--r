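# Shared fixtures: tiny documents built in code, small generated corpora,
# and reduced-size model configurations for fast training smoke tests.

# Fixture cache: expensive trained models are built once per test run and
# shared across blocks that only need "some trained model of this shape".
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

tiny_doc <- function(doc_id = "d1") {
  text <- "Patient started Zalprex 50 mg for cardelia . Patient developed nausea after starting Zalprex ."
  ents <- tibble::tibble(
    id = c("T1", "T2", "T3", "T4", "T5"),
    type = c("Medication", "Dosage", "Indication", "ADE", "Medication"),
    start = c(16L, 24L, 34L, 63L, 85L),
    end = c(23L, 29L, 42L, 69L, 92L),
    text = c("Zalprex", "50 mg", "cardelia", "nausea", "Zalprex"))
  rels <- tibble::tibble(
    id = c("R1", "R2", "R3"),
    type = c("Dosage-Medication", "Medication-Indication", "Medication-ADE"),
    arg1 = c("T2", "T1", "T5"),
    arg2 = c("T1", "T3", "T4"))
  ade_document(doc_id, text, ents, rels)
}

small_corpus <- function(n_docs = 16L, seed = 7L, ...) {
  generate_corpus(gen_config(n_docs = n_docs, seed = seed, ...))
}

fast_ner_cfg <- function(...) {
  ade_small_ner_config(epochs = 3L, stop_loss = NULL, ...)
}

fast_re_cfg <- function(...) {
  ade_small_re_config(epochs = 3L, stop_loss = NULL, ...)
}

# Independent reference implementation of the BMES repair rule, written as
# a direct left-to-right transcription used only as a test oracle.
reference_decode <- function(labels) {
  spans <- list()
  open <- NULL # c(start, last, type)
  flush <- function() {
    if (!is.null(open)) {
      spans[[length(spans) + 1L]] <<- open
      open <<- NULL
    }
  }
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    if (lab == "O") { flush(); next }
    tag <- substr(lab, 1L, 1L)
    typ <- substring(lab, 3L)
    if (tag == "S") {
      flush()
      spans[[length(spans) + 1L]] <- list(i, i, typ)
    } else if (tag == "B") {
      flush()
      open <- list(i, i, typ)
    } else if (!is.null(open) && open[[3L]] == typ) {
      open[[2L]] <- i
      if (tag == "E") flush()
    } else {
      flush() # orphan M/E acts as O
    }
  }
  flush()
  spans
}
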