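#' Controlled vocabularies for interaction records
#'
#' Three closed status vocabularies govern record fields:
#'
#' * `organism_status` — establishment status of each organism, aligned to
#'   the Darwin Core `establishmentMeans` property (Native, Naturalised,
#'   Introduced, Invasive, Captivity, Managed).
#' * `interaction_status` — whether the interaction was recorded in the
#'   wild or under various captive conditions.
#' * `importance` — the importance of the interaction to humans (economic,
#'   medical, veterinary categories).
#'
#' A fourth, hierarchical vocabulary supplies the typed relations
#' themselves (see [load_interaction_vocabulary()]).
#'
#' @name vocabularies
NULL

STATUS_VOCAB_NAMES <- c("organism_status", "interaction_status", "importance")

BUILTIN_STATUS <- c(
  table1 = "organism-status.tsv",
  table2 = "interaction-status.tsv",
  table3 = "importance.tsv"
)
BUILTIN_STATUS_NAME <- c(
  table1 = "organism_status",
  table2 = "interaction_status",
  table3 = "importance"
)
BUILTIN_INTERACTION <- c("ro-core" = "ro-core.tsv")

vocab_file <- function(file) {
  system.file("extdata", "vocabularies", file,
    package = "ecointeractions", mustWork = TRUE
  )
}

new_status_vocabulary <- function(entries, name) {
  stopifnot(name %in% STATUS_VOCAB_NAMES)
  out <- as_tibble(entries[, c("label", "description")])
  out$description <- na_to_empty(out$description)
  dup <- duplicated(tolower(out$label))
  if (any(dup)) {
    abort(sprintf(
      "duplicate vocabulary label '%s' at entry %d",
      out$label[which(dup)[1]], which(dup)[1]
    ))
  }
  structure(out,
    class = c("status_vocabulary", class(out)),
    vocab_name = name
  )
}

#' Load a closed status vocabulary
#'
#' Reads a two-column (label, description) tab-separated file, or one of
#' the packaged vocabularies by built-in name: `"table1"` (organism
#' establishment status), `"table2"` (wild/captive interaction status),
#' `"table3"` (importance to humans).
#'
#' @param source Path to a TSV file with a `label`/`description` header,
#'   or a built-in name.
#' @param name For file sources, which vocabulary this is: one of
#'   `"organism_status"`, `"interaction_status"`, `"importance"`.
#'   Ignored for built-ins.
#' @return A `status_vocabulary`: a tibble of `label` and `description`
#'   in source order, with the vocabulary name attached.
#' @examples
#' load_status_vocabulary("table1")$label
#' @export
load_status_vocabulary <- function(source, name = "organism_status") {
  if (source %in% names(BUILTIN_STATUS)) {
    path <- vocab_file(BUILTIN_STATUS[[source]])
    name <- BUILTIN_STATUS_NAME[[source]]
  } else if (file.exists(source)) {
    path <- source
    name <- match.arg(name, STATUS_VOCAB_NAMES)
  } else {
    abort(sprintf("unknown built-in vocabulary or missing file: '%s'", source))
  }
  entries <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (!all(c("label", "description") %in% names(entries))) {
    abort(sprintf("'%s': expected a label/description header", path))
  }
  dup <- which(duplicated(tolower(entries$label)))
  if (length(dup) > 0) {
    # +1 for the header line
    abort(sprintf(
      "'%s': duplicate label '%s' at line %d",
      path, entries$label[dup[1]], dup[1] + 1
    ))
  }
  new_status_vocabulary(entries, name)
}

#' Write a status vocabulary to a TSV file
#'
#' Byte-stable inverse of [load_status_vocabulary()].
#'
#' @param vocab A `status_vocabulary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_status_vocabulary <- function(vocab, path) {
  lines <- c(
    "label\tdescription",
    paste(vocab$label, na_to_empty(vocab$description), sep = "\t")
  )
  write_lines_lf(lines, path)
  invisible(path)
}

#' Construct an interaction-type term
#'
#' A relation term pairs a human-readable label (e.g. `"eats"`) with its
#' ontology IRI, the label and IRI of its inverse relation (`"eaten by"`),
#' and an optional parent term making the vocabulary hierarchical
#' (`"ectoparasite of"` is a child of `"parasite of"`).
#'
#' @param label Relation name.
#' @param uri IRI for the relation (treated as an opaque string).
#' @param inverse_label Name of the reverse relation; may equal `label`
#'   for symmetric relations.
#' @param inverse_uri IRI of the reverse relation.
#' @param parent_label Label of the parent term, or `NA` for a root.
#' @return A one-row tibble with class `interaction_type_term`.
#' @export
interaction_type_term <- function(label, uri, inverse_label, inverse_uri,
                                  parent_label = NA_character_) {
  out <- tibble(
    label = trimws(label),
    uri = trimws(uri),
    inverse_label = trimws(inverse_label),
    inverse_uri = trimws(inverse_uri),
    parent_label = if (is.na(parent_label) || !nzchar(trimws(parent_label))) {
      NA_character_
    } else {
      trimws(parent_label)
    }
  )
  structure(out, class = c("interaction_type_term", class(out)))
}

# Invariant checks shared by the loader and add_term(): unique labels and
# URIs, resolvable parents, an acyclic (forest) hierarchy, and symmetric
# inverse pairing.
validate_interaction_vocabulary <- function(terms) {
  dup <- which(duplicated(tolower(terms$label)))
  if (length(dup) > 0) {
    abort(sprintf("duplicate term label '%s'", terms$label[dup[1]]))
  }
  dup_uri <- which(duplicated(terms$uri))
  if (length(dup_uri) > 0) {
    abort(sprintf("duplicate term uri '%s'", terms$uri[dup_uri[1]]))
  }
  has_parent <- !is.na(terms$parent_label)
  bad_parent <- has_parent & !resolves_in(terms$parent_label, terms$label)
  if (any(bad_parent)) {
    abort(sprintf(
      "term '%s' has unresolvable parent '%s'",
      terms$label[which(bad_parent)[1]],
      terms$parent_label[which(bad_parent)[1]]
    ))
  }
  # acyclicity: peel roots repeatedly; anything left sits on a cycle
  remaining <- terms$label
  parent <- canonical_label(terms$parent_label, terms$label)
  names(parent) <- terms$label
  repeat {
    roots <- remaining[is.na(parent[remaining]) |
      !(parent[remaining] %in% remaining)]
    if (length(roots) == 0) break
    remaining <- setdiff(remaining, roots)
  }
  if (length(remaining) > 0) {
    abort(sprintf(
      "parent hierarchy contains a cycle through: %s",
      paste(sort(remaining), collapse = ", ")
    ))
  }
  # inverse symmetry: if A names B as its inverse, B must name A
  inv <- canonical_label(terms$inverse_label, terms$label)
  unresolved <- is.na(inv)
  if (any(unresolved)) {
    abort(sprintf(
      "term '%s' has unresolvable inverse '%s'",
      terms$label[which(unresolved)[1]],
      terms$inverse_label[which(unresolved)[1]]
    ))
  }
  inv_of_inv <- inv[match(inv, terms$label)]
  broken <- inv_of_inv != terms$label
  if (any(broken)) {
    i <- which(broken)[1]
    abort(sprintf(
      "asymmetric inverse pair: '%s' lists '%s' as inverse, but '%s' lists '%s'",
      terms$label[i], inv[i], inv[i], inv_of_inv[i]
    ))
  }
  invisible(terms)
}

new_interaction_vocabulary <- function(terms) {
  terms <- as_tibble(terms[, c(
    "label", "uri", "inverse_label", "inverse_uri", "parent_label"
  )])
  validate_interaction_vocabulary(terms)
  structure(terms, class = c("interaction_vocabulary", class(terms)))
}

#' Load a hierarchical interaction-type vocabulary
#'
#' Reads a five-column tab-separated file (`label`, `uri`,
#' `inverse_label`, `inverse_uri`, `parent_label`; empty parent = root),
#' or the packaged default by built-in name `"ro-core"`, a hand-curated
#' set of Relations Ontology inter-organism relations including
#' eats/eaten by and the parasite-of subtree (ectoparasite of,
#' endoparasite of) with their inverses.
#'
#' All invariants are verified at load time: unique labels and IRIs, an
#' acyclic single-parent hierarchy, and symmetric inverse pairing.
#'
#' @param source Path to a vocabulary TSV, or `"ro-core"`.
#' @return An `interaction_vocabulary` tibble of terms.
#' @examples
#' ro <- load_interaction_vocabulary("ro-core")
#' inverse_of(ro, "eats")
#' @export
load_interaction_vocabulary <- function(source = "ro-core") {
  if (source %in% names(BUILTIN_INTERACTION)) {
    path <- vocab_file(BUILTIN_INTERACTION[[source]])
  } else if (file.exists(source)) {
    path <- source
  } else {
    abort(sprintf("unknown built-in vocabulary or missing file: '%s'", source))
  }
  terms <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  needed <- c("label", "uri", "inverse_label", "inverse_uri", "parent_label")
  if (!all(needed %in% names(terms))) {
    abort(sprintf(
      "'%s': expected header columns %s", path, paste(needed, collapse = ", ")
    ))
  }
  terms$parent_label <- empty_to_na(terms$parent_label)
  new_interaction_vocabulary(terms)
}

#' Write an interaction-type vocabulary to a TSV file
#'
#' Byte-stable inverse of [load_interaction_vocabulary()].
#'
#' @param vocab An `interaction_vocabulary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_vocabulary <- function(vocab, path) {
  lines <- c(
    "label\turi\tinverse_label\tinverse_uri\tparent_label",
    paste(vocab$label, vocab$uri, vocab$inverse_label, vocab$inverse_uri,
      na_to_empty(vocab$parent_label),
      sep = "\t"
    )
  )
  write_lines_lf(lines, path)
  invisible(path)
}

resolve_term <- function(vocab, label) {
  hit <- canonical_label(label, vocab$label)
  if (is.na(hit)) {
    abort(sprintf("unknown interaction-type label '%s'", label))
  }
  hit
}

#' All descendants of a term, including itself
#'
#' Reflexive-transitive closure down the term hierarchy; used by the
#' query engine so a search for `"parasite of"` also retrieves records
#' typed with the narrower `"ectoparasite of"`.
#'
#' @param vocab An `interaction_vocabulary`.
#' @param label A term label (matched case-insensitively).
#' @return Character vector of canonical labels: the term plus all
#'   transitive children.
#' @export
descendants <- function(vocab, label) {
  start <- resolve_term(vocab, label)
  parent <- canonical_label(vocab$parent_label, vocab$label)
  out <- start
  frontier <- start
  while (length(frontier) > 0) {
    kids <- vocab$label[!is.na(parent) & parent %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' The inverse of a relation term
#'
#' @param vocab An `interaction_vocabulary`.
#' @param label A term label (matched case-insensitively).
#' @return The canonical label of the inverse term; for symmetric terms,
#'   the term itself.  `inverse_of(inverse_of(x)) == x` for every loaded
#'   term.
#' @export
inverse_of <- function(vocab, label) {
  hit <- resolve_term(vocab, label)
  inv <- vocab$inverse_label[match(hit, vocab$label)]
  canonical_label(inv, vocab$label)
}

term_uri <- function(vocab, label) {
  hit <- resolve_term(vocab, label)
  vocab$uri[match(hit, vocab$label)]
}

#' Add a term to an interaction-type vocabulary
#'
#' The updated vocabulary is re-validated in full, so label/IRI
#' uniqueness, hierarchy acyclicity and inverse symmetry hold after any
#' sequence of additions.  If the new term's `inverse_label` names an
#' existing term, that term's inverse pointers are rewritten to point
#' back at the new term.  A term whose inverse does not yet exist cannot
#' be added alone (every term's inverse must resolve); pass the partner
#' as `inverse` to add the pair atomically.
#'
#' @param vocab An `interaction_vocabulary`.
#' @param term An [interaction_type_term()].
#' @param inverse Optional [interaction_type_term()] added together with
#'   `term`, for introducing a new inverse pair in one call.
#' @return The updated `interaction_vocabulary`.
#' @export
add_term <- function(vocab, term, inverse = NULL) {
  incoming <- term
  if (!is.null(inverse)) incoming <- rbind(incoming, inverse)
  for (i in seq_len(nrow(incoming))) {
    if (resolves_in(incoming$label[i], vocab$label)) {
      abort(sprintf("term label '%s' already exists", incoming$label[i]))
    }
    if (incoming$uri[i] %in% vocab$uri) {
      abort(sprintf("term uri '%s' already exists", incoming$uri[i]))
    }
    if (!is.na(incoming$parent_label[i]) &&
      tolower(incoming$parent_label[i]) == tolower(incoming$label[i])) {
      abort(sprintf(
        "term '%s' cannot be its own parent", incoming$label[i]
      ))
    }
  }
  terms <- rbind(
    as_tibble(vocab)[, names(incoming)],
    as_tibble(incoming)
  )
  # repoint an existing inverse target back at the newly added term
  for (i in seq_len(nrow(incoming))) {
    tgt <- match(tolower(incoming$inverse_label[i]), tolower(vocab$label))
    if (!is.na(tgt)) {
      terms$inverse_label[tgt] <- incoming$label[i]
      terms$inverse_uri[tgt] <- incoming$uri[i]
    }
  }
  new_interaction_vocabulary(terms)
}

#' Lint an interaction-type vocabulary
#'
#' Reports stylistic inconsistencies that are not errors, currently one
#' rule: a child term whose inverse does not descend from its parent's
#' inverse (e.g. `"ectoparasite of"` under `"parasite of"` whose inverse
#' sits outside the `"parasitized by"` subtree).  Nothing constrains this
#' formally, but curated vocabularies normally mirror the hierarchy on
#' both sides.
#'
#' @param vocab An `interaction_vocabulary`.
#' @return Character vector of warning messages (empty when clean).
#' @export
lint_interaction_vocabulary <- function(vocab) {
  msgs <- character(0)
  for (i in seq_len(nrow(vocab))) {
    p <- vocab$parent_label[i]
    if (is.na(p)) next
    inv_child <- inverse_of(vocab, vocab$label[i])
    inv_parent <- inverse_of(vocab, p)
    if (!(inv_child %in% descendants(vocab, inv_parent))) {
      msgs <- c(msgs, sprintf(
        "inverse of '%s' ('%s') is not under the inverse of its parent '%s' ('%s')",
        vocab$label[i], inv_child, p, inv_parent
      ))
    }
  }
  msgs
}

#' Load the full default vocabulary set
#'
#' Bundles the three packaged status vocabularies and the packaged
#' interaction-type vocabulary; this is the default against which
#' records are created and validated.
#'
#' @return A named list with elements `organism_status`,
#'   `interaction_status`, `importance` and `interaction_types`, of class
#'   `vocabulary_set`.
#' @export
default_vocabularies <- function() {
  structure(
    list(
      organism_status = load_status_vocabulary("table1"),
      interaction_status = load_status_vocabulary("table2"),
      importance = load_status_vocabulary("table3"),
      interaction_types = load_interaction_vocabulary("ro-core")
    ),
    class = "vocabulary_set"
  )
}
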