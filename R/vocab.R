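# Integer-indexed vocabularies. Index 1 is always the unknown symbol (and
# doubles as padding for characters), so lookup of out-of-vocabulary items
# is total and never an error.

vocab_build <- function(items, min_count = 1L) {
  tab <- table(items)
  keep <- names(tab)[tab >= min_count]
  c("<unk>", sort(keep))
}

vocab_index <- function(vocab, items) {
  idx <- match(items, vocab)
  idx[is.na(idx)] <- 1L
  idx
}

char_indices <- function(token, char_vocab) {
  vocab_index(char_vocab, strsplit(token, "", fixed = TRUE)[[1L]])
}

# Read word embeddings in whitespace-separated text format:
# one line per word, "word v1 v2 ... vd".
#' Read word embeddings in plain-text word2vec format
#'
#' @param path File with one `word v1 ... vd` line per word (an optional
#'   leading `n d` header line is skipped).
#' @return List with character vector `words` and numeric matrix `vectors`
#'   (one row per word).
#' @export
read_word_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  first <- strsplit(lines[1L], "\\s+")[[1L]]
  if (length(first) == 2L && !is.na(suppressWarnings(as.numeric(first[2L])))) {
    lines <- lines[-1L] # header "n d"
  }
  parts <- strsplit(lines, "\\s+")
  words <- vapply(parts, `[[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(parts[[1L]]) - 1L)))
  list(words = words, vectors = vecs)
}
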