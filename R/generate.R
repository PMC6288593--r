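# Seeded generator of clinical-style documents over the 9-type/7-relation
# annotation schema. Text comes from closed synthetic lexicons (invented
# drug and symptom names; no real patient language), assembled from
# templates whose wording determines the gold annotation, so every stage of
# the pipeline is learnable by construction while remaining non-trivial:
# the SSLIF class dominates ADE by an order of magnitude, ADE and SSLIF
# draw from the same symptom lexicon (context alone disambiguates), a
# configurable fraction of relations spans sentences, and distractor
# sentences put relation-like wording ("stopped secondary to ...") next to
# pairs that bear no relation.

lex_medications <- function() {
  c("Zalprex", "Cortivan", "Medrazol", "Velcamid", "Doxitrel", "Aprenol",
    "Lunestra", "Carbidex", "Fenopril", "Tacrinex", "Zubernib", "Olmerta",
    "Praxiban", "Quenolol", "Riftamab", "Sorvalin", "Tredexol", "Uvistat",
    "Vanlumab", "Wortezib")
}

lex_symptom_adjs <- function() {
  c("renal", "hepatic", "acute", "chronic", "peripheral", "abdominal")
}

lex_symptom_nouns <- function() {
  c("failure", "rash", "neuropathy", "fatigue", "edema", "nausea",
    "dizziness", "anemia", "cough", "headache", "pruritus", "tremor",
    "confusion", "insomnia", "myalgia", "dyspnea")
}

lex_indications <- function() {
  c("bronterosis", "cardelia", "dermatax", "gastrenia", "hematov",
    "nephrosia", "pulmonitis", "ostealgia", "neurodyne", "lymphora")
}

lex_severity <- function() c("mild", "moderate", "severe", "worsening")

lex_route <- function() c("orally", "intravenously", "topically",
                          "subcutaneously")

lex_freq_units <- function() c("daily", "weekly", "nightly")

#' Configuration for the synthetic corpus generator
#'
#' Defaults define the package's reference study conditions: 250 documents
#' split 200 train / 50 test, 4-8 sentences per document, a sentence-
#' template mixture whose expected SSLIF:ADE entity ratio is 10:1
#' (the SSLIF sign/symptom/disease class dominates, mirroring real
#' clinical annotation), a tenth of ADE relations expressed across
#' sentences, and a 5% rate of distractor sentences.
#'
#' @param n_docs Total documents generated.
#' @param test_fraction Fraction of documents assigned to the test split.
#' @param sentences_per_doc Integer range `c(min, max)`.
#' @param template_weights Named sampling weights for the sentence
#'   templates `med_attr`, `indication`, `ade`, `sslif`, `cross`.
#' @param intersentence_fraction Fraction of ADE/indication relation
#'   statements split across sentences.
#' @param max_relation_gap Sentence gap for inter-sentence relations (>= 1).
#' @param noise_rate Probability that a sentence is followed by a
#'   distractor sentence (relation-like wording, no relation).
#' @param seed Integer seed; a fixed seed reproduces the corpus
#'   byte-for-byte.
#' @return A list of class `ade_gen_config`.
#' @export
gen_config <- function(n_docs = 250L, test_fraction = 0.2,
                       sentences_per_doc = c(4L, 8L),
                       template_weights = c(med_attr = 0.22,
                                            indication = 0.13,
                                            ade = 0.077,
                                            sslif = 0.48,
                                            cross = 0.093),
                       intersentence_fraction = 0.1,
                       max_relation_gap = 2L,
                       noise_rate = 0.05,
                       seed = 13L) {
  stopifnot(n_docs >= 1L, test_fraction >= 0, test_fraction < 1,
            length(sentences_per_doc) == 2L,
            sentences_per_doc[1L] >= 1L,
            sentences_per_doc[2L] >= sentences_per_doc[1L],
            all(template_weights >= 0), sum(template_weights) > 0,
            intersentence_fraction >= 0, intersentence_fraction <= 1,
            max_relation_gap >= 1L, noise_rate >= 0, noise_rate <= 1)
  structure(list(n_docs = as.integer(n_docs), test_fraction = test_fraction,
                 sentences_per_doc = as.integer(sentences_per_doc),
                 template_weights = template_weights,
                 intersentence_fraction = intersentence_fraction,
                 max_relation_gap = as.integer(max_relation_gap),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "ade_gen_config")
}

# A sentence under construction: words plus entity/relation markers with
# word-index spans. Entities: list(type, from, to). Relations reference
# local entity list positions in canonical signature order.
mk_symptom <- function() {
  if (stats::runif(1) < 0.45) {
    c(sample(lex_symptom_adjs(), 1L), sample(lex_symptom_nouns(), 1L))
  } else {
    sample(lex_symptom_nouns(), 1L)
  }
}

gen_sentence <- function(kind) {
  words <- character(0)
  ents <- list()
  rels <- list()
  put <- function(ws) {
    from <- length(words) + 1L
    words <<- c(words, ws)
    c(from, length(words))
  }
  ent <- function(type, ws) {
    sp <- put(ws)
    ents[[length(ents) + 1L]] <<- list(type = type, from = sp[1L],
                                       to = sp[2L])
    length(ents)
  }
  rel <- function(type, a1, a2) {
    rels[[length(rels) + 1L]] <<- list(type = type, arg1 = a1, arg2 = a2)
  }
  if (kind == "med_attr") {
    put("Patient"); put("started")
    m <- ent("Medication", sample(lex_medications(), 1L))
    if (stats::runif(1) < 0.9) {
      d <- ent("Dosage", c(as.character(sample(c(5L, 10L, 25L, 50L, 100L,
                                                 250L), 1L)), "mg"))
      rel("Dosage-Medication", d, m)
    }
    if (stats::runif(1) < 0.6) {
      r <- ent("Route", sample(lex_route(), 1L))
      rel("Route-Medication", r, m)
    }
    if (stats::runif(1) < 0.6) {
      f <- ent("Frequency", c(sample(c("once", "twice"), 1L),
                              sample(lex_freq_units(), 1L)))
      rel("Frequency-Medication", f, m)
    }
    if (stats::runif(1) < 0.5) {
      put("for")
      u <- ent("Duration", c(as.character(sample(2:8, 1L)),
                             sample(c("weeks", "days", "months"), 1L)))
      rel("Duration-Medication", u, m)
    }
    put(".")
  } else if (kind == "indication") {
    put("Patient"); put("was"); put("given")
    m <- ent("Medication", sample(lex_medications(), 1L))
    put("for")
    i <- ent("Indication", sample(lex_indications(), 1L))
    rel("Medication-Indication", m, i)
    put(".")
  } else if (kind == "ade") {
    put("Patient"); put("developed")
    sev <- NULL
    if (stats::runif(1) < 0.5) sev <- ent("Severity", sample(lex_severity(), 1L))
    a <- ent("ADE", mk_symptom())
    put("after"); put("starting")
    m <- ent("Medication", sample(lex_medications(), 1L))
    rel("Medication-ADE", m, a)
    if (!is.null(sev)) rel("Severity-ADE", sev, a)
    put(".")
  } else if (kind == "sslif") {
    lead <- sample(c("History of", "Patient reports", "Examination showed"),
                   1L)
    put(strsplit(lead, " ", fixed = TRUE)[[1L]])
    ent("SSLIF", mk_symptom())
    if (stats::runif(1) < 0.5) {
      put("and")
      ent("SSLIF", mk_symptom())
    }
    put(".")
  } else if (kind == "cross") {
    put("Patient"); put("started")
    m1 <- ent("Medication", sample(lex_medications(), 1L))
    d1 <- ent("Dosage", c(as.character(sample(c(5L, 10L, 25L, 50L), 1L)),
                          "mg"))
    put("and")
    m2 <- ent("Medication", sample(setdiff(lex_medications(),
                                           words[ents[[m1]]$from]), 1L))
    d2 <- ent("Dosage", c(as.character(sample(c(100L, 200L, 250L, 500L),
                                              1L)), "mg"))
    rel("Dosage-Medication", d1, m1)
    rel("Dosage-Medication", d2, m2)
    put(".")
  } else if (kind == "distractor") {
    put("He"); put("remained"); put("on")
    ent("Medication", sample(lex_medications(), 1L))
    put(","); put("stopped"); put("secondary"); put("to")
    ent("SSLIF", mk_symptom())
    put(".")
  } else if (kind == "filler") {
    put(strsplit(sample(c("Follow up was arranged .",
                          "Labs were reviewed .",
                          "He was seen in clinic ."), 1L),
                 " ", fixed = TRUE)[[1L]])
  } else {
    stop("unknown sentence kind: ", kind)
  }
  list(words = words, ents = ents, rels = rels)
}

# Inter-sentence variant of the ade/indication statement: returns a list of
# sentences; relations on the last sentence reference entities by
# (sentence, local index) pairs resolved at assembly.
gen_intersentence <- function(kind, gap) {
  first <- gen_sentence("filler")
  if (kind == "ade") {
    s1 <- list(words = c("Patient", "started",
                         sample(lex_medications(), 1L), "."),
               ents = list(list(type = "Medication", from = 3L, to = 3L)),
               rels = list())
    sym <- mk_symptom()
    n2 <- c("He", "later", "developed", sym, ".")
    s2 <- list(words = n2,
               ents = list(list(type = "ADE", from = 4L,
                                to = 3L + length(sym))),
               rels = list())
    cross <- list(type = "Medication-ADE", from_sent = 1L, from_ent = 1L,
                  to_ent = 1L)
  } else {
    s1 <- list(words = c("Patient", "was", "given",
                         sample(lex_medications(), 1L), "."),
               ents = list(list(type = "Medication", from = 4L, to = 4L)),
               rels = list())
    ind <- sample(lex_indications(), 1L)
    s2 <- list(words = c("This", "was", "for", ind, "."),
               ents = list(list(type = "Indication", from = 4L, to = 4L)),
               rels = list())
    cross <- list(type = "Medication-Indication", from_sent = 1L,
                  from_ent = 1L, to_ent = 1L)
  }
  fillers <- replicate(gap - 1L, gen_sentence("filler"), simplify = FALSE)
  list(sentences = c(list(s1), fillers, list(s2)), cross = cross)
}

assemble_document <- function(doc_id, sent_list, cross_rels, split) {
  text <- ""
  ents <- list()
  rels <- list()
  ent_ids <- list() # per sentence: local index -> global entity row
  for (si in seq_along(sent_list)) {
    s <- sent_list[[si]]
    starts <- integer(length(s$words))
    pos <- nchar(text)
    if (si > 1L) { text <- paste0(text, " "); pos <- pos + 1L }
    for (w in seq_along(s$words)) {
      if (w > 1L) { text <- paste0(text, " "); pos <- pos + 1L }
      starts[w] <- pos
      text <- paste0(text, s$words[w])
      pos <- pos + nchar(s$words[w])
    }
    ends <- starts + nchar(s$words)
    local <- integer(length(s$ents))
    for (e in seq_along(s$ents)) {
      en <- s$ents[[e]]
      ents[[length(ents) + 1L]] <- tibble::tibble(
        id = paste0("T", length(ents) + 1L), type = en$type,
        start = starts[en$from], end = ends[en$to],
        text = paste(s$words[en$from:en$to], collapse = " "))
      local[e] <- length(ents)
    }
    ent_ids[[si]] <- local
    for (r in s$rels) {
      rels[[length(rels) + 1L]] <- tibble::tibble(
        id = paste0("R", length(rels) + 1L), type = r$type,
        arg1 = paste0("T", local[r$arg1]), arg2 = paste0("T", local[r$arg2]))
    }
  }
  for (cr in cross_rels) {
    rels[[length(rels) + 1L]] <- tibble::tibble(
      id = paste0("R", length(rels) + 1L), type = cr$type,
      arg1 = paste0("T", ent_ids[[cr$sent1]][cr$ent1]),
      arg2 = paste0("T", ent_ids[[cr$sent2]][cr$ent2]))
  }
  ade_document(doc_id, text,
               entities = if (length(ents)) dplyr::bind_rows(ents) else
                 empty_entities(),
               relations = if (length(rels)) dplyr::bind_rows(rels) else
                 empty_relations(),
               split = split)
}

gen_document <- function(doc_id, cfg, split) {
  n_sent <- sample(cfg$sentences_per_doc[1L]:cfg$sentences_per_doc[2L], 1L)
  kinds <- sample(names(cfg$template_weights), n_sent, replace = TRUE,
                  prob = cfg$template_weights)
  sents <- list()
  cross <- list()
  for (k in kinds) {
    if (k %in% c("ade", "indication") &&
          stats::runif(1) < cfg$intersentence_fraction) {
      gap <- sample.int(cfg$max_relation_gap, 1L)
      block <- gen_intersentence(k, gap)
      base <- length(sents)
      sents <- c(sents, block$sentences)
      cross[[length(cross) + 1L]] <- list(
        type = block$cross$type,
        sent1 = base + 1L, ent1 = 1L,
        sent2 = base + length(block$sentences), ent2 = 1L)
    } else {
      sents[[length(sents) + 1L]] <- gen_sentence(k)
    }
    if (stats::runif(1) < cfg$noise_rate) {
      sents[[length(sents) + 1L]] <- gen_sentence("distractor")
    }
  }
  assemble_document(doc_id, sents, cross, split)
}

#' Generate a synthetic annotated corpus
#'
#' Draws documents from the template mixture of `cfg` under its seed and
#' splits them into train and test sets. The same configuration and seed
#' reproduce the corpus exactly.
#'
#' @param cfg A [gen_config()].
#' @return A list of class `ade_corpus` with `train` and `test` (lists of
#'   `ade_document`) and the `config`.
#' @export
generate_corpus <- function(cfg = gen_config()) {
  stopifnot(inherits(cfg, "ade_gen_config"))
  stream <- rng_stream(derive_seed(cfg$seed, "corpus"))
  n_test <- round(cfg$n_docs * cfg$test_fraction)
  docs <- with_stream(stream, {
    lapply(seq_len(cfg$n_docs), function(i) {
      split <- if (i > cfg$n_docs - n_test) "test" else "train"
      gen_document(sprintf("doc%04d", i), cfg, split)
    })
  })
  structure(list(train = docs[seq_len(cfg$n_docs - n_test)],
                 test = if (n_test > 0) docs[(cfg$n_docs - n_test + 1L):
                                               cfg$n_docs] else list(),
                 config = cfg),
            class = "ade_corpus")
}

#' @export
print.ade_corpus <- function(x, ...) {
  cat("<ade_corpus> ", length(x$train), " train / ", length(x$test),
      " test documents (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Summary statistics of an annotated corpus
#'
#' @param docs A list of `ade_document` (e.g. `corpus$train`), or an
#'   `ade_corpus` (train and test pooled).
#' @return A list with tibbles `entities` (per-type counts over all nine
#'   types), `relations` (per-type counts over all seven types), and
#'   `gap_hist` (relation sentence-gap histogram).
#' @export
corpus_stats <- function(docs) {
  if (inherits(docs, "ade_corpus")) docs <- c(docs$train, docs$test)
  docs <- as_doc_list(docs)
  ents <- corpus_entities(docs)
  rels <- corpus_relations(docs)
  etab <- tibble::tibble(type = ade_entity_types())
  etab$n <- vapply(etab$type, function(t) {
    if (nrow(ents)) sum(ents$type == t) else 0L
  }, 0L)
  rtab <- tibble::tibble(type = ade_relation_types()$type)
  rtab$n <- vapply(rtab$type, function(t) {
    if (nrow(rels)) sum(rels$type == t) else 0L
  }, 0L)
  gaps <- integer(0)
  for (d in docs) {
    if (nrow(d$relations) == 0) next
    toks <- tokenize_text(d$text)
    sent_at <- function(start, end) {
      i <- which(toks$start < end & toks$end > start)
      toks$sentence_index[i[1L]]
    }
    s1 <- mapply(sent_at,
                 d$entities$start[match(d$relations$arg1, d$entities$id)],
                 d$entities$end[match(d$relations$arg1, d$entities$id)])
    s2 <- mapply(sent_at,
                 d$entities$start[match(d$relations$arg2, d$entities$id)],
                 d$entities$end[match(d$relations$arg2, d$entities$id)])
    gaps <- c(gaps, abs(s2 - s1))
  }
  gap_hist <- if (length(gaps)) {
    dplyr::count(tibble::tibble(gap = gaps), .data$gap, name = "n")
  } else {
    tibble::tibble(gap = integer(), n = integer())
  }
  list(entities = etab, relations = rtab, gap_hist = gap_hist)
}
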