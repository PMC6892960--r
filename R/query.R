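#' Faceted querying of interaction datasets
#'
#' Filters combine by conjunction, as in a faceted-search interface.
#' Two retrieval aids exploit the vocabulary structure, both on by
#' default: hierarchy expansion (a query for "parasite of" also returns
#' records typed with the narrower "ectoparasite of") and inverse
#' matching (a record stored as louse-parasite-of-host is also found by
#' the host-side query, with role-specific criteria evaluated against
#' the reversed view).
#'
#' @name query
NULL

FACET_FIELDS <- c(
  "interaction_type", "subject_status", "object_status",
  "interaction_status", "importance", "subject_taxon", "object_taxon"
)

#' Build query criteria
#'
#' All arguments are optional; present criteria combine by conjunction.
#'
#' @param taxon_name Exact scientific name, matched against a role's
#'   taxon name or any element of its classification path.
#' @param taxon_side Which side `taxon_name` applies to: `"either"`
#'   (default), `"subject"` or `"object"`.
#' @param interaction_type Relation label.
#' @param expand_hierarchy Match descendant terms of `interaction_type`
#'   too (default `TRUE`).
#' @param match_inverse Also match records whose reversed view satisfies
#'   all criteria (default `TRUE`).
#' @param subject_status_in,subject_status_not_in Establishment-status
#'   labels the subject must / must not have (`"unknown"` allowed).
#' @param object_status_in,object_status_not_in Likewise for the object.
#' @param interaction_status_in Wild/captive status labels.
#' @param importance_in Importance labels.
#' @param locality_name_contains Substring matched case-insensitively
#'   against the locality name.
#' @return A `query_criteria` object.
#' @export
query_criteria <- function(taxon_name = NULL,
                           taxon_side = c("either", "subject", "object"),
                           interaction_type = NULL,
                           expand_hierarchy = TRUE,
                           match_inverse = TRUE,
                           subject_status_in = NULL,
                           subject_status_not_in = NULL,
                           object_status_in = NULL,
                           object_status_not_in = NULL,
                           interaction_status_in = NULL,
                           importance_in = NULL,
                           locality_name_contains = NULL) {
  taxon_side <- match.arg(taxon_side)
  overlap_s <- intersect(
    tolower(subject_status_in), tolower(subject_status_not_in)
  )
  overlap_o <- intersect(
    tolower(object_status_in), tolower(object_status_not_in)
  )
  if (length(overlap_s) > 0 || length(overlap_o) > 0) {
    abort("status _in and _not_in sets must be disjoint")
  }
  structure(
    list(
      taxon_name = taxon_name, taxon_side = taxon_side,
      interaction_type = interaction_type,
      expand_hierarchy = isTRUE(expand_hierarchy),
      match_inverse = isTRUE(match_inverse),
      subject_status_in = subject_status_in,
      subject_status_not_in = subject_status_not_in,
      object_status_in = object_status_in,
      object_status_not_in = object_status_not_in,
      interaction_status_in = interaction_status_in,
      importance_in = importance_in,
      locality_name_contains = locality_name_contains
    ),
    class = "query_criteria"
  )
}

# resolve every criterion label before evaluation; lookup errors name
# the offending label
check_criteria_labels <- function(criteria, vocabularies) {
  chk <- function(labels, vocab, what) {
    if (is.null(labels)) return(invisible())
    labels <- setdiff(tolower(labels), "unknown")
    bad <- labels[!resolves_in(labels, vocab$label)]
    if (length(bad) > 0) {
      abort(sprintf("unknown %s label '%s'", what, bad[1]))
    }
  }
  if (!is.null(criteria$interaction_type)) {
    resolve_term(vocabularies$interaction_types, criteria$interaction_type)
  }
  chk(criteria$subject_status_in, vocabularies$organism_status, "organism-status")
  chk(criteria$subject_status_not_in, vocabularies$organism_status, "organism-status")
  chk(criteria$object_status_in, vocabularies$organism_status, "organism-status")
  chk(criteria$object_status_not_in, vocabularies$organism_status, "organism-status")
  chk(criteria$interaction_status_in, vocabularies$interaction_status, "interaction-status")
  chk(criteria$importance_in, vocabularies$importance, "importance")
  invisible(criteria)
}

# flatten a dataset once per query into a tibble for vectorised
# evaluation; classification paths become list-columns
records_table <- function(dataset) {
  recs <- dataset$records
  chr <- function(f) vapply(recs, f, character(1))
  tibble(
    uuid = chr(function(r) r$uuid),
    subject_name = chr(function(r) r$subject$taxon$name),
    object_name = chr(function(r) r$object$taxon$name),
    subject_path = lapply(recs, function(r) r$subject$taxon$classification_path),
    object_path = lapply(recs, function(r) r$object$taxon$classification_path),
    subject_status = chr(function(r) r$subject$establishment_status),
    object_status = chr(function(r) r$object$establishment_status),
    interaction_type = chr(function(r) r$interaction_type),
    interaction_status = chr(function(r) r$interaction_status),
    importance = chr(function(r) {
      if (is.na(r$importance)) NA_character_ else r$importance
    }),
    locality_name = chr(function(r) {
      if (is.null(r$locality)) NA_character_ else r$locality$name
    })
  )
}

# evaluate the conjunction of all criteria against one orientation of
# the flattened table (columns already swapped for the reversed view)
match_view <- function(tbl, criteria, vocabularies) {
  n <- nrow(tbl)
  ok <- rep(TRUE, n)

  if (!is.null(criteria$taxon_name)) {
    name <- criteria$taxon_name
    hit_side <- function(names, paths) {
      names == name | vapply(paths, function(p) name %in% p, logical(1))
    }
    sub_hit <- hit_side(tbl$subject_name, tbl$subject_path)
    obj_hit <- hit_side(tbl$object_name, tbl$object_path)
    ok <- ok & switch(criteria$taxon_side,
      subject = sub_hit,
      object = obj_hit,
      either = sub_hit | obj_hit
    )
  }

  if (!is.null(criteria$interaction_type)) {
    vocab <- vocabularies$interaction_types
    wanted <- if (criteria$expand_hierarchy) {
      descendants(vocab, criteria$interaction_type)
    } else {
      resolve_term(vocab, criteria$interaction_type)
    }
    ok <- ok & tbl$interaction_type %in% wanted
  }

  in_set <- function(values, set) {
    tolower(values) %in% tolower(set)
  }
  if (!is.null(criteria$subject_status_in)) {
    ok <- ok & in_set(tbl$subject_status, criteria$subject_status_in)
  }
  if (!is.null(criteria$subject_status_not_in)) {
    ok <- ok & !in_set(tbl$subject_status, criteria$subject_status_not_in)
  }
  if (!is.null(criteria$object_status_in)) {
    ok <- ok & in_set(tbl$object_status, criteria$object_status_in)
  }
  if (!is.null(criteria$object_status_not_in)) {
    ok <- ok & !in_set(tbl$object_status, criteria$object_status_not_in)
  }
  if (!is.null(criteria$interaction_status_in)) {
    ok <- ok & in_set(tbl$interaction_status, criteria$interaction_status_in)
  }
  if (!is.null(criteria$importance_in)) {
    ok <- ok & !is.na(tbl$importance) &
      in_set(tbl$importance, criteria$importance_in)
  }
  if (!is.null(criteria$locality_name_contains)) {
    ok <- ok & !is.na(tbl$locality_name) &
      grepl(tolower(criteria$locality_name_contains),
        tolower(tbl$locality_name),
        fixed = TRUE
      )
  }
  ok
}

# the reversed orientation: roles swapped, type replaced by its inverse
reversed_table <- function(tbl, vocab) {
  inv <- vapply(unique(tbl$interaction_type), function(t) {
    tryCatch(inverse_of(vocab, t), error = function(e) NA_character_)
  }, character(1))
  tibble(
    uuid = tbl$uuid,
    subject_name = tbl$object_name,
    object_name = tbl$subject_name,
    subject_path = tbl$object_path,
    object_path = tbl$subject_path,
    subject_status = tbl$object_status,
    object_status = tbl$subject_status,
    interaction_type = unname(inv[tbl$interaction_type]),
    interaction_status = tbl$interaction_status,
    importance = tbl$importance,
    locality_name = tbl$locality_name
  )
}

#' Filter a dataset
#'
#' Returns the records satisfying the conjunction of all present
#' criteria, in dataset order.  With `match_inverse` on, a record also
#' matches when its reversed view (roles swapped, relation inverted)
#' satisfies all criteria; role-specific criteria are then evaluated
#' against the reversed roles.
#'
#' @param dataset An `interaction_dataset`.
#' @param criteria A [query_criteria()].
#' @return A list of `interaction_record`s.
#' @export
filter_records <- function(dataset, criteria = query_criteria()) {
  stopifnot(inherits(criteria, "query_criteria"))
  check_criteria_labels(criteria, dataset$vocabularies)
  if (length(dataset$records) == 0) return(list())
  tbl <- records_table(dataset)
  hit <- match_view(tbl, criteria, dataset$vocabularies)
  if (criteria$match_inverse) {
    rtbl <- reversed_table(tbl, dataset$vocabularies$interaction_types)
    usable <- !is.na(rtbl$interaction_type)
    rhit <- rep(FALSE, nrow(tbl))
    rhit[usable] <- match_view(
      rtbl[usable, , drop = FALSE], criteria, dataset$vocabularies
    )
    hit <- hit | rhit
  }
  dataset$records[hit]
}

#' Facet counts over a query result
#'
#' Counts the distinct values of one field over `filter_records(dataset,
#' criteria)`.  Zero counts are omitted; the `"unknown"` sentinel
#' appears as its own facet value; records without an importance value
#' are omitted from the `importance` facet (the field is optional).  For
#' always-valued fields the counts sum to the result-set size.
#'
#' @param dataset An `interaction_dataset`.
#' @param field One of `"interaction_type"`, `"subject_status"`,
#'   `"object_status"`, `"interaction_status"`, `"importance"`,
#'   `"subject_taxon"`, `"object_taxon"`.
#' @param criteria A [query_criteria()]; defaults to no filtering.
#' @return A named integer vector (value → count), sorted by decreasing
#'   count then label.
#' @export
facet_counts <- function(dataset, field, criteria = query_criteria()) {
  if (!(field %in% FACET_FIELDS)) {
    abort(sprintf(
      "unrecognised facet field '%s' (expected one of: %s)",
      field, paste(FACET_FIELDS, collapse = ", ")
    ))
  }
  hits <- filter_records(dataset, criteria)
  if (length(hits) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  values <- vapply(hits, function(r) {
    switch(field,
      interaction_type = r$interaction_type,
      subject_status = r$subject$establishment_status,
      object_status = r$object$establishment_status,
      interaction_status = r$interaction_status,
      importance = if (is.na(r$importance)) NA_character_ else r$importance,
      subject_taxon = r$subject$taxon$name,
      object_taxon = r$object$taxon$name
    )
  }, character(1))
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(values)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}
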