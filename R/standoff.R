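# Standoff annotation I/O. One .ann per .txt, matched by basename, UTF-8.
# Entity line:   T<n> \t TYPE START END \t SURFACE
# Relation line: R<n> \t RELTYPE Arg1:T<i> Arg2:T<j>

#' Read a document from text + standoff annotation files
#'
#' Parses a plain-text file and its companion standoff annotation file into
#' an [ade_document()]. Character offsets in the annotation file are 0-based
#' and half-open; every entity's surface string is verified against the
#' document substring it claims to cover.
#'
#' @param text_path Path to the `.txt` file.
#' @param ann_path Path to the `.ann` file; defaults to `text_path` with its
#'   extension replaced by `.ann`.
#' @param split Split tag to record on the document.
#' @return An `ade_document`.
#' @export
read_standoff <- function(text_path, ann_path = NULL, split = "none") {
  if (is.null(ann_path)) ann_path <- sub("\\.txt$", ".ann", text_path)
  if (!file.exists(text_path)) stop("text file not found: ", text_path)
  if (!file.exists(ann_path)) stop("annotation file not found: ", ann_path)
  text <- paste(readLines(text_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  ents <- list(); rels <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (grepl("^T", fields[1L])) {
      if (length(fields) != 3L) {
        stop("malformed entity line ", ln, " in ", ann_path, ": ", line)
      }
      head <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
      if (length(head) != 3L) {
        stop("malformed entity line ", ln, " in ", ann_path, ": ", line)
      }
      start <- suppressWarnings(as.integer(head[2L]))
      end <- suppressWarnings(as.integer(head[3L]))
      if (is.na(start) || is.na(end)) {
        stop("malformed offsets on line ", ln, " in ", ann_path)
      }
      if (start < 0L || end > nchar(text) || start >= end) {
        stop("offsets out of range on line ", ln, " in ", ann_path)
      }
      surface <- fields[3L]
      if (substr_many(text, start, end) != surface) {
        stop("surface/offset mismatch on line ", ln, " in ", ann_path,
             ": annotation says '", surface, "', text has '",
             substr_many(text, start, end), "'")
      }
      ents[[length(ents) + 1L]] <- tibble::tibble(
        id = fields[1L], type = head[1L], start = start, end = end,
        text = surface)
    } else if (grepl("^R", fields[1L])) {
      if (length(fields) != 2L) {
        stop("malformed relation line ", ln, " in ", ann_path, ": ", line)
      }
      head <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
      if (length(head) != 3L || !grepl("^Arg1:", head[2L]) ||
            !grepl("^Arg2:", head[3L])) {
        stop("malformed relation line ", ln, " in ", ann_path, ": ", line)
      }
      rels[[length(rels) + 1L]] <- tibble::tibble(
        id = fields[1L], type = head[1L],
        arg1 = sub("^Arg1:", "", head[2L]),
        arg2 = sub("^Arg2:", "", head[3L]))
    } else {
      stop("unrecognised annotation line ", ln, " in ", ann_path, ": ", line)
    }
  }
  entities <- if (length(ents)) dplyr::bind_rows(ents) else empty_entities()
  relations <- if (length(rels)) dplyr::bind_rows(rels) else empty_relations()
  missing <- setdiff(c(relations$arg1, relations$arg2), entities$id)
  if (length(missing) > 0) {
    stop("relation references undefined entity '", missing[1L], "' in ",
         ann_path)
  }
  doc_id <- sub("\\.txt$", "", basename(text_path))
  ade_document(doc_id, text, entities, relations, split = split)
}

#' Write a document as text + standoff annotation files
#'
#' Inverse of [read_standoff()]: emits `<doc_id>.txt` and `<doc_id>.ann`
#' under `out_dir`, parseable back into an equal document.
#'
#' @param doc An `ade_document`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector with `text_path` and
#'   `ann_path`.
#' @export
write_standoff <- function(doc, out_dir) {
  stopifnot(inherits(doc, "ade_document"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  text_path <- file.path(out_dir, paste0(doc$doc_id, ".txt"))
  ann_path <- file.path(out_dir, paste0(doc$doc_id, ".ann"))
  writeLines(doc$text, text_path, useBytes = TRUE, sep = "")
  ents <- doc$entities
  rels <- doc$relations
  lines <- character(0)
  if (nrow(ents) > 0) {
    lines <- c(lines, paste0(ents$id, "\t", ents$type, " ", ents$start, " ",
                             ents$end, "\t", ents$text))
  }
  if (nrow(rels) > 0) {
    lines <- c(lines, paste0(rels$id, "\t", rels$type, " Arg1:", rels$arg1,
                             " Arg2:", rels$arg2))
  }
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(c(text_path = text_path, ann_path = ann_path))
}

#' Read every text/annotation pair in a directory
#'
#' @param dir Directory containing matched `.txt`/`.ann` pairs.
#' @param split Split tag to record on each document.
#' @return A list of `ade_document` objects, ordered by file name.
#' @export
read_standoff_dir <- function(dir, split = "none") {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, read_standoff, split = split)
}

#' Write a corpus of documents to a directory
#'
#' @param docs List of `ade_document` objects.
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_standoff_dir <- function(docs, out_dir) {
  for (d in as_doc_list(docs)) write_standoff(d, out_dir)
  invisible(out_dir)
}
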