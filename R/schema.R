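# The annotation schema: 9 clinical entity types and 7 typed binary
# relations between them. Each relation name determines its argument types
# (e.g. Severity-ADE takes a Severity first argument and an ADE second), so
# argument order is canonical throughout the package.

#' Entity types of the annotation schema
#'
#' The nine entity types used for adverse-drug-event extraction from
#' clinical narrative: `Medication`, `Indication`, `Frequency`, `Severity`,
#' `Dosage`, `Duration`, `Route`, `ADE` (adverse drug event), and `SSLIF`
#' (any sign, symptom, or disease that is neither an ADE nor an Indication).
#'
#' @return Character vector of the nine type names.
#' @export
#' @examples
#' ade_entity_types()
ade_entity_types <- function() {
  c("Medication", "Indication", "Frequency", "Severity",
    "Dosage", "Duration", "Route", "ADE", "SSLIF")
}

#' Relation types of the annotation schema
#'
#' The seven relation types, each with a fixed argument-type signature.
#' `arg1_type` is the attribute-like argument (Dosage, Route, Frequency,
#' Duration, Severity) or Medication; `arg2_type` completes the pair.
#'
#' @return A tibble with columns `type`, `arg1_type`, `arg2_type`.
#' @export
#' @examples
#' ade_relation_types()
ade_relation_types <- function() {
  tibble::tibble(
    type = c("Dosage-Medication", "Route-Medication", "Frequency-Medication",
             "Duration-Medication", "Medication-Indication", "Medication-ADE",
             "Severity-ADE"),
    arg1_type = c("Dosage", "Route", "Frequency", "Duration",
                  "Medication", "Medication", "Severity"),
    arg2_type = c("Medication", "Medication", "Medication", "Medication",
                  "Indication", "ADE", "ADE")
  )
}

# Lookup: unordered entity-type pair -> relation type name (or NA).
# Signatures are pairwise distinct as unordered pairs, so this is total.
relation_for_pair <- function(t1, t2) {
  sig <- ade_relation_types()
  key <- paste(pmin(t1, t2), pmax(t1, t2))
  skey <- paste(pmin(sig$arg1_type, sig$arg2_type),
                pmax(sig$arg1_type, sig$arg2_type))
  sig$type[match(key, skey)]
}

#' Validate a document against the annotation schema
#'
#' Checks that every entity uses one of the nine schema types, that every
#' relation uses one of the seven schema relation types, and that each
#' relation's arguments exist and carry the entity types its signature
#' demands. Violations are returned, never raised.
#'
#' @param doc An `ade_document`.
#' @return A tibble with columns `kind`, `id`, `message`; zero rows when the
#'   document conforms to the schema.
#' @export
#' @examples
#' d <- ade_document("d1", "Renal Failure",
#'   entities = tibble::tibble(id = "T1", type = "SSLIF", start = 0L, end = 13L,
#'                             text = "Renal Failure"))
#' validate_schema(d) # zero rows
validate_schema <- function(doc) {
  stopifnot(inherits(doc, "ade_document"))
  out <- list()
  ents <- doc$entities
  rels <- doc$relations
  bad_t <- ents[!ents$type %in% ade_entity_types(), ]
  if (nrow(bad_t) > 0) {
    out[[length(out) + 1L]] <- tibble::tibble(
      kind = "entity_type", id = bad_t$id,
      message = paste0("unknown entity type '", bad_t$type, "'"))
  }
  sig <- ade_relation_types()
  etype <- stats::setNames(ents$type, ents$id)
  for (i in seq_len(nrow(rels))) {
    r <- rels[i, ]
    srow <- sig[sig$type == r$type, ]
    if (nrow(srow) == 0L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "relation_type", id = r$id,
        message = paste0("unknown relation type '", r$type, "'"))
      next
    }
    for (side in c("arg1", "arg2")) {
      aid <- r[[side]]
      want <- srow[[paste0(side, "_type")]]
      if (!aid %in% names(etype)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "dangling_argument", id = r$id,
          message = paste0(side, " references missing entity '", aid, "'"))
      } else if (etype[[aid]] != want) {
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "argument_type", id = r$id,
          message = paste0(side, " of ", r$type, " must be ", want,
                           ", got ", etype[[aid]]))
      }
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(kind = character(), id = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}
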