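# Deterministic tokenisation, sentence splitting and rule-based POS
# tagging. The tokenizer is regex-based (word characters, numbers with
# internal ./,, or single punctuation marks) and records exact character
# offsets so annotations can be aligned and predictions written back as
# standoff offsets.

#' Tokenize a document and split it into sentences
#'
#' Splits text into sentences at sentence-final punctuation followed by
#' whitespace (or a newline), and each sentence into tokens. Offsets are
#' 0-based half-open and satisfy `substring(text, start+1, end) == text` for
#' every token. Part-of-speech tags are filled by the bundled rule-based
#' tagger.
#'
#' @param text Document text.
#' @param tagger A function `(character vector of token texts) -> character
#'   vector of POS tags`; defaults to [rule_pos_tag()]. Any external tagger
#'   with this signature can be plugged in.
#' @return A tibble with one row per token: `sentence_index` (1-based),
#'   `token_index` (document-global, 1-based), `text`, `start`, `end`,
#'   `pos`, `initial_capital`.
#' @export
#' @examples
#' tokenize_text("Renal Failure.")
tokenize_text <- function(text, tagger = rule_pos_tag) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    return(tibble::tibble(sentence_index = integer(), token_index = integer(),
                          text = character(), start = integer(),
                          end = integer(), pos = character(),
                          initial_capital = logical()))
  }
  # token pattern: numbers (with internal . or /), words, or single symbol
  pat <- "[0-9]+(?:[./][0-9]+)*|[A-Za-z]+(?:'[A-Za-z]+)?|[^A-Za-z0-9\\s]"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) { # whitespace only: no tokens
    return(tokenize_text(""))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  ends <- starts + lens
  toks <- substring(text, starts + 1L, ends)
  # sentence boundary after . ! ? when followed by whitespace/EOL
  n <- length(toks)
  sent <- integer(n)
  s <- 1L
  for (i in seq_len(n)) {
    sent[i] <- s
    if (toks[i] %in% c(".", "!", "?")) {
      follow <- if (ends[i] >= nchar(text)) "" else
        substring(text, ends[i] + 1L, ends[i] + 1L)
      if (follow == "" || grepl("^\\s$", follow)) s <- s + 1L
    }
  }
  tibble::tibble(
    sentence_index = sent,
    token_index = seq_len(n),
    text = toks,
    start = starts,
    end = ends,
    pos = tagger(toks),
    initial_capital = grepl("^[A-Z]", toks)
  )
}

#' Rule-based part-of-speech tagger
#'
#' A deterministic tagger built from a closed-class lexicon plus suffix
#' heuristics, so the package needs no model download and tagging is
#' reproducible bit-for-bit. Coverage targets the Penn tagset's common
#' tags: e.g. "Renal" is tagged `JJ` (adjectival `-al` suffix), numerals
#' `CD`, punctuation tags itself.
#'
#' @param tokens Character vector of token texts.
#' @return Character vector of POS tags, same length.
#' @export
#' @examples
#' rule_pos_tag(c("Renal", "Failure", "50", "."))
rule_pos_tag <- function(tokens) {
  lex <- c(
    the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", his = "PRP$",
    her = "PRP$", their = "PRP$", its = "PRP$", he = "PRP", she = "PRP",
    it = "PRP", they = "PRP", patient = "NN", of = "IN", "for" = "IN",
    after = "IN", before = "IN", with = "IN", without = "IN", on = "IN",
    "in" = "IN", to = "TO", and = "CC", or = "CC", but = "CC", was = "VBD",
    were = "VBD", is = "VBZ", are = "VBP", been = "VBN", be = "VB",
    has = "VBZ", have = "VBP", had = "VBD", not = "RB", no = "DT",
    denies = "VBZ", reports = "VBZ", developed = "VBD", started = "VBD",
    stopped = "VBD", given = "VBN", takes = "VBZ", taking = "VBG",
    daily = "RB", twice = "RB", once = "RB", secondary = "JJ", due = "JJ",
    mg = "NN", ml = "NN", mcg = "NN", units = "NNS", weeks = "NNS",
    days = "NNS", months = "NNS", week = "NN", day = "NN", month = "NN"
  )
  vapply(tokens, function(tk) {
    low <- tolower(tk)
    if (!is.na(lex[low])) return(unname(lex[low]))
    if (grepl("^[0-9]+(?:[./][0-9]+)*$", tk)) return("CD")
    if (grepl("^[^A-Za-z0-9]+$", tk)) return(tk) # punctuation tags itself
    if (grepl("(al|ous|ive|ic|ary|able)$", low)) return("JJ")
    if (grepl("ly$", low)) return("RB")
    if (grepl("ing$", low)) return("VBG")
    if (grepl("ed$", low)) return("VBN")
    if (grepl("s$", low) && nchar(low) > 3L) return("NNS")
    if (grepl("^[A-Z]", tk)) return("NNP")
    "NN"
  }, character(1L), USE.NAMES = FALSE)
}

# Split a token table into a list of per-sentence tibbles.
split_sentences <- function(tokens) {
  if (nrow(tokens) == 0) return(list())
  unname(split(tokens, tokens$sentence_index))
}
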