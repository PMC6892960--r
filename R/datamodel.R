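#' Domain constructors for interaction records
#'
#' An interaction record documents one typed interaction between two
#' organisms: a subject role and an object role (each a taxon plus an
#' establishment status and optional organism part), the relation term,
#' the wild/captive status under which the interaction was recorded, an
#' optional importance value, supporting evidence, and an optional
#' locality.  Every record carries a UUID that persists through export
#' and aggregation so corrections can be traced back to the source.
#'
#' @name datamodel
NULL

EVIDENCE_KINDS <- c("reference", "specimen", "observation")

#' Construct a taxon concept
#'
#' @param name Scientific name (non-empty after trimming).
#' @param rank Free-text rank label, optional.
#' @param classification_path Ordered character vector of ancestor names
#'   from root to the taxon itself, optional.  Stored per record side
#'   because different sources use different classifications for the
#'   same hosts.
#' @param external_id External identifier string, optional.
#' @return A `taxon_concept` list.
#' @export
taxon_concept <- function(name, rank = NA_character_,
                          classification_path = character(0),
                          external_id = NA_character_) {
  structure(
    list(
      name = trimws(as.character(name)),
      rank = as.character(rank),
      classification_path = as.character(classification_path),
      external_id = as.character(external_id)
    ),
    class = "taxon_concept"
  )
}

#' Construct an organism role
#'
#' One side of an interaction: a taxon together with its establishment
#' status and, where the source records it, the anatomical part involved
#' (a louse restricted to its host's wings, a caterpillar feeding on
#' flowers).  The part is kept verbatim as free text; no controlled
#' anatomy vocabulary is imposed.
#'
#' @param taxon A [taxon_concept()], or a scientific name which is
#'   promoted to one.
#' @param establishment_status A label from the organism-status
#'   vocabulary, or `"unknown"`.
#' @param organism_part Verbatim free-text part name, optional.
#' @return An `organism_role` list.
#' @export
organism_role <- function(taxon, establishment_status = "unknown",
                          organism_part = NA_character_) {
  if (is.character(taxon)) taxon <- taxon_concept(taxon)
  stopifnot(inherits(taxon, "taxon_concept"))
  structure(
    list(
      taxon = taxon,
      establishment_status = as.character(establishment_status),
      organism_part = as.character(organism_part)
    ),
    class = "organism_role"
  )
}

#' Construct an evidence source
#'
#' Interactions are backed by bibliographic references, museum specimens
#' or direct observations.
#'
#' @param kind One of `"reference"`, `"specimen"`, `"observation"`.
#' @param citation Free-text citation or catalogue identifier.
#' @param identifier External identifier (DOI, catalogue number),
#'   optional.
#' @return An `evidence_source` list.
#' @export
evidence_source <- function(kind, citation, identifier = NA_character_) {
  structure(
    list(
      kind = as.character(kind),
      citation = as.character(citation),
      identifier = as.character(identifier)
    ),
    class = "evidence_source"
  )
}

#' Construct a locality
#'
#' @param name Free-text place name, optional.
#' @param latitude,longitude Decimal degrees (WGS84 assumed); both
#'   present or both absent.
#' @return A `locality` list.
#' @export
locality <- function(name = NA_character_, latitude = NA_real_,
                     longitude = NA_real_) {
  structure(
    list(
      name = as.character(name),
      latitude = as.numeric(latitude),
      longitude = as.numeric(longitude)
    ),
    class = "locality"
  )
}

new_interaction_record <- function(uuid, subject, object, interaction_type,
                                   interaction_status, importance, evidence,
                                   locality) {
  structure(
    list(
      uuid = uuid,
      subject = subject,
      object = object,
      interaction_type = interaction_type,
      interaction_status = interaction_status,
      importance = importance,
      evidence = evidence,
      locality = locality
    ),
    class = "interaction_record"
  )
}

dataset_uuids <- function(dataset) {
  vapply(dataset$records, function(r) r$uuid, character(1))
}

#' Create an interaction record
#'
#' The interaction type must resolve in the active vocabulary (an error
#' names the offending label otherwise); status labels that resolve are
#' canonicalised to the vocabulary's casing, and unset statuses default
#' to the `"unknown"` sentinel.  A fresh random UUID is generated unless
#' an explicit one is supplied; an explicit UUID already present in
#' `dataset` is a uniqueness error.
#'
#' @param subject,object [organism_role()]s (a bare scientific name is
#'   promoted).
#' @param interaction_type Relation label, e.g. `"eats"`.
#' @param vocabularies A vocabulary set, by default
#'   [default_vocabularies()].
#' @param interaction_status Wild/captive status label or `"unknown"`.
#' @param importance Importance label, or `NA` for none.  At most one
#'   value.
#' @param evidence A list of [evidence_source()]s (a single one is
#'   wrapped).
#' @param locality A [locality()], optional.
#' @param uuid Explicit UUID to preserve, optional.
#' @param dataset Optional dataset against which explicit-UUID
#'   uniqueness is checked.
#' @return An `interaction_record`.
#' @examples
#' r <- create_record(
#'   organism_role("Carausius morosus", "Introduced"),
#'   organism_role("Rosa sp.", "Introduced"),
#'   "eats"
#' )
#' r$subject$establishment_status
#' @export
create_record <- function(subject, object, interaction_type,
                          vocabularies = default_vocabularies(),
                          interaction_status = "unknown",
                          importance = NA_character_,
                          evidence = list(),
                          locality = NULL,
                          uuid = NULL,
                          dataset = NULL) {
  if (is.character(subject)) subject <- organism_role(subject)
  if (is.character(object)) object <- organism_role(object)
  stopifnot(
    inherits(subject, "organism_role"),
    inherits(object, "organism_role")
  )
  type <- resolve_term(vocabularies$interaction_types, interaction_type)
  if (inherits(evidence, "evidence_source")) evidence <- list(evidence)

  if (length(importance) > 1) {
    abort("importance is single-valued: supply at most one label")
  }

  canon_status <- function(x, vocab) {
    if (is.na(x) || tolower(trimws(x)) == "unknown") return("unknown")
    hit <- canonical_label(x, vocab$label)
    if (is.na(hit)) x else hit
  }
  subject$establishment_status <- canon_status(
    subject$establishment_status, vocabularies$organism_status
  )
  object$establishment_status <- canon_status(
    object$establishment_status, vocabularies$organism_status
  )
  interaction_status <- canon_status(
    interaction_status, vocabularies$interaction_status
  )
  if (!is.na(importance)) {
    hit <- canonical_label(importance, vocabularies$importance$label)
    importance <- if (is.na(hit)) importance else hit
  }

  if (is.null(uuid)) {
    uuid <- new_uuid()
  } else {
    if (!is_valid_uuid(uuid)) {
      abort(sprintf("'%s' is not a syntactically valid UUID", uuid))
    }
    if (!is.null(dataset) && uuid %in% dataset_uuids(dataset)) {
      abort(sprintf("uuid '%s' already present in dataset", uuid))
    }
  }

  new_interaction_record(
    uuid = uuid, subject = subject, object = object,
    interaction_type = type, interaction_status = interaction_status,
    importance = importance, evidence = evidence, locality = locality
  )
}

#' Validate a record against the vocabularies
#'
#' Violations are returned, never raised: an empty result means every
#' vocabulary-bound field resolves and all structural invariants hold.
#' Each violation names the field, the offending value and the rule.
#'
#' @param record An `interaction_record`.
#' @param vocabularies A vocabulary set.
#' @return A tibble with columns `field`, `value`, `rule`; zero rows for
#'   a valid record.
#' @export
validate_record <- function(record, vocabularies = default_vocabularies()) {
  v <- no_violations()
  add <- function(field, value, rule) {
    v <<- rbind(v, violation(field, value, rule))
  }

  if (!is_valid_uuid(record$uuid)) {
    add("uuid", record$uuid, "uuid must be syntactically valid")
  }

  check_role <- function(role, side) {
    tx <- role$taxon
    if (is.na(tx$name) || !nzchar(trimws(tx$name))) {
      add(
        paste0(side, ".taxon.name"), tx$name,
        "taxon name must be non-empty after trimming"
      )
    }
    if (length(tx$classification_path) > 0 &&
      tail(tx$classification_path, 1) != tx$name) {
      add(
        paste0(side, ".taxon.classification_path"),
        paste(tx$classification_path, collapse = "|"),
        "last element of classification_path must equal the taxon name"
      )
    }
    st <- role$establishment_status
    if (!identical(st, "unknown") &&
      !resolves_in(st, vocabularies$organism_status$label)) {
      add(
        paste0(side, ".establishment_status"), st,
        "establishment_status must be 'unknown' or an organism-status label"
      )
    }
  }
  check_role(record$subject, "subject")
  check_role(record$object, "object")

  if (!resolves_in(
    record$interaction_type, vocabularies$interaction_types$label
  )) {
    add(
      "interaction_type", record$interaction_type,
      "interaction_type must resolve in the interaction-type vocabulary"
    )
  }
  if (!identical(record$interaction_status, "unknown") &&
    !resolves_in(
      record$interaction_status, vocabularies$interaction_status$label
    )) {
    add(
      "interaction_status", record$interaction_status,
      "interaction_status must be 'unknown' or an interaction-status label"
    )
  }
  if (length(record$importance) > 1) {
    add(
      "importance", paste(record$importance, collapse = ";"),
      "importance is single-valued"
    )
  } else if (!is.na(record$importance) &&
    !resolves_in(record$importance, vocabularies$importance$label)) {
    add(
      "importance", record$importance,
      "importance must resolve in the importance vocabulary"
    )
  }

  for (ev in record$evidence) {
    if (!(ev$kind %in% EVIDENCE_KINDS)) {
      add(
        "evidence.kind", ev$kind,
        "evidence kind must be reference, specimen or observation"
      )
    }
    if (is.na(ev$citation) || !nzchar(trimws(ev$citation))) {
      add("evidence.citation", ev$citation, "evidence citation must be non-empty")
    }
  }

  loc <- record$locality
  if (!is.null(loc)) {
    if (is.na(loc$latitude) != is.na(loc$longitude)) {
      add(
        "locality", paste0(loc$latitude, ",", loc$longitude),
        "latitude and longitude must both be present or both absent"
      )
    }
    if (!is.na(loc$latitude) && (loc$latitude < -90 || loc$latitude > 90)) {
      add("locality.latitude", loc$latitude, "latitude must lie in [-90, 90]")
    }
    if (!is.na(loc$longitude) &&
      (loc$longitude < -180 || loc$longitude > 180)) {
      add(
        "locality.longitude", loc$longitude,
        "longitude must lie in [-180, 180]"
      )
    }
    if ((is.na(loc$name) || !nzchar(loc$name)) && is.na(loc$latitude)) {
      add(
        "locality", NA_character_,
        "locality needs a name or a coordinate pair"
      )
    }
  }

  v
}

#' Reversed view of a record
#'
#' Returns a non-persisted view with subject and object swapped and the
#' interaction type replaced by its inverse ("eaten by" for "eats");
#' UUID, statuses, evidence and locality are unchanged.  Applying the
#' view twice yields the original record, field for field.
#'
#' @param record An `interaction_record`.
#' @param vocab An `interaction_vocabulary`; defaults to the packaged
#'   one.
#' @return An `interaction_record` view (not added to any dataset).
#' @export
reversed_view <- function(record, vocab = load_interaction_vocabulary("ro-core")) {
  inv <- inverse_of(vocab, record$interaction_type)
  out <- record
  out$subject <- record$object
  out$object <- record$subject
  out$interaction_type <- inv
  out
}

#' Create an interaction dataset
#'
#' An ordered, UUID-keyed collection of records plus the vocabularies
#' they validate against and a free-form provenance metadata block.
#'
#' @param records List of `interaction_record`s.
#' @param vocabularies A vocabulary set.
#' @param metadata Named list of provenance keys (source name, version,
#'   licence, ...).
#' @return An `interaction_dataset`.
#' @export
new_dataset <- function(records = list(),
                        vocabularies = default_vocabularies(),
                        metadata = list()) {
  ds <- structure(
    list(records = list(), vocabularies = vocabularies, metadata = metadata),
    class = "interaction_dataset"
  )
  if (length(records) > 0) ds <- add_records(ds, records)
  ds
}

#' Append records to a dataset
#'
#' Record order is preserved; a duplicate UUID is a uniqueness error.
#'
#' @param dataset An `interaction_dataset`.
#' @param records An `interaction_record` or list of them.
#' @return The updated dataset.
#' @export
add_records <- function(dataset, records) {
  if (inherits(records, "interaction_record")) records <- list(records)
  seen <- dataset_uuids(dataset)
  for (r in records) {
    stopifnot(inherits(r, "interaction_record"))
    if (r$uuid %in% seen) {
      abort(sprintf("uuid '%s' already present in dataset", r$uuid))
    }
    seen <- c(seen, r$uuid)
  }
  dataset$records <- c(dataset$records, records)
  dataset
}

#' Validate every record in a dataset
#'
#' @param dataset An `interaction_dataset`.
#' @return A tibble of violations with a leading `uuid` column; zero
#'   rows when the dataset is clean.
#' @export
validate_dataset <- function(dataset) {
  out <- purrr::map_dfr(dataset$records, function(r) {
    v <- validate_record(r, dataset$vocabularies)
    if (nrow(v) == 0) return(NULL)
    cbind(tibble(uuid = r$uuid), v)
  })
  if (nrow(out) == 0) {
    out <- cbind(tibble(uuid = character(0)), no_violations())
  }
  as_tibble(out)
}

#' @export
length.interaction_dataset <- function(x) length(x$records)

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf(
    "<interaction_dataset> %d record(s), %d interaction-type term(s)\n",
    length(x$records), nrow(x$vocabularies$interaction_types)
  ))
  if (length(x$metadata) > 0) {
    cat(
      "metadata:",
      paste(names(x$metadata), unlist(x$metadata),
        sep = "=", collapse = "; "
      ), "\n"
    )
  }
  invisible(x)
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf(
    "<interaction_record %s>\n  %s [%s] --%s--> %s [%s]\n",
    x$uuid,
    x$subject$taxon$name, x$subject$establishment_status,
    x$interaction_type,
    x$object$taxon$name, x$object$establishment_status
  ))
  invisible(x)
}

#' @importFrom utils tail
NULL
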