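# Independent oracles for the property tests.  These deliberately take
# the naive route (per-record loops, recursive traversal) so they share
# no code with the vectorised implementations they check.

# -- brute-force descendants via per-node ancestor walks -----------------
# independent route: a term y descends from x iff x appears on y's walk
# to the root, so descendants(x) = { y : x \in ancestors(y) }.
oracle_ancestor_sets <- function(vocab) {
  labels <- vocab$label
  pidx <- match(vocab$parent_label, labels)
  lapply(seq_along(labels), function(i) {
    out <- labels[i]
    cur <- pidx[i]
    while (!is.na(cur)) {
      out <- c(out, labels[cur])
      cur <- pidx[cur]
    }
    out
  })
}

oracle_descendants <- function(vocab, label,
                               anc = oracle_ancestor_sets(vocab)) {
  vocab$label[vapply(anc, function(s) label %in% s, logical(1))]
}

# -- random vocabulary forests -------------------------------------------
# terms t001..tNNN; consecutive pairs are mutual inverses (odd leftover is
# self-inverse); each term's parent is a strictly earlier term or absent,
# so the parent graph is a forest by construction.
random_forest_tsv <- function(n, path) {
  labels <- sprintf("t%04d", seq_len(n))
  uris <- sprintf("http://example.org/term/%04d", seq_len(n))
  inverse <- labels
  inv_uri <- uris
  i <- 1
  while (i + 1 <= n) {
    inverse[i] <- labels[i + 1]
    inverse[i + 1] <- labels[i]
    inv_uri[i] <- uris[i + 1]
    inv_uri[i + 1] <- uris[i]
    i <- i + 2
  }
  parent <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    if (j > 1 && stats::runif(1) < 0.8) {
      parent[j] <- labels[sample.int(j - 1, 1)]
    }
  }
  lines <- c(
    "label\turi\tinverse_label\tinverse_uri\tparent_label",
    paste(labels, uris, inverse, inv_uri,
      ifelse(is.na(parent), "", parent),
      sep = "\t"
    )
  )
  writeLines(lines, path)
  path
}

# -- naive record-by-record query evaluator ------------------------------
# evaluates one orientation of a record against the full conjunction
oracle_match_one <- function(rec, criteria, vocab, wanted_types) {
  if (!is.null(criteria$taxon_name)) {
    hit_role <- function(role) {
      role$taxon$name == criteria$taxon_name ||
        criteria$taxon_name %in% role$taxon$classification_path
    }
    ok <- switch(criteria$taxon_side,
      subject = hit_role(rec$subject),
      object = hit_role(rec$object),
      either = hit_role(rec$subject) || hit_role(rec$object)
    )
    if (!ok) return(FALSE)
  }
  if (!is.null(criteria$interaction_type)) {
    if (!(rec$interaction_type %in% wanted_types)) return(FALSE)
  }
  lc <- function(x) tolower(x)
  if (!is.null(criteria$subject_status_in) &&
    !(lc(rec$subject$establishment_status) %in% lc(criteria$subject_status_in))) {
    return(FALSE)
  }
  if (!is.null(criteria$subject_status_not_in) &&
    lc(rec$subject$establishment_status) %in% lc(criteria$subject_status_not_in)) {
    return(FALSE)
  }
  if (!is.null(criteria$object_status_in) &&
    !(lc(rec$object$establishment_status) %in% lc(criteria$object_status_in))) {
    return(FALSE)
  }
  if (!is.null(criteria$object_status_not_in) &&
    lc(rec$object$establishment_status) %in% lc(criteria$object_status_not_in)) {
    return(FALSE)
  }
  if (!is.null(criteria$interaction_status_in) &&
    !(lc(rec$interaction_status) %in% lc(criteria$interaction_status_in))) {
    return(FALSE)
  }
  if (!is.null(criteria$importance_in)) {
    if (is.na(rec$importance) ||
      !(lc(rec$importance) %in% lc(criteria$importance_in))) {
      return(FALSE)
    }
  }
  if (!is.null(criteria$locality_name_contains)) {
    if (is.null(rec$locality) || is.na(rec$locality$name) ||
      !grepl(tolower(criteria$locality_name_contains),
        tolower(rec$locality$name),
        fixed = TRUE
      )) {
      return(FALSE)
    }
  }
  TRUE
}

oracle_filter <- function(dataset, criteria) {
  vocab <- dataset$vocabularies$interaction_types
  wanted_types <- if (is.null(criteria$interaction_type)) {
    NULL
  } else if (criteria$expand_hierarchy) {
    oracle_descendants(vocab, criteria$interaction_type)
  } else {
    criteria$interaction_type
  }
  keep <- logical(length(dataset$records))
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    hit <- oracle_match_one(rec, criteria, vocab, wanted_types)
    if (!hit && criteria$match_inverse) {
      rev <- reversed_view(rec, vocab)
      hit <- oracle_match_one(rev, criteria, vocab, wanted_types)
    }
    keep[i] <- hit
  }
  dataset$records[keep]
}

# random but always-valid criteria drawn from a dataset's value space
random_criteria <- function(dataset) {
  vs <- dataset$vocabularies
  types <- vs$interaction_types$label
  statuses <- c(vs$organism_status$label, "unknown")
  istatuses <- vs$interaction_status$label
  importances <- vs$importance$label
  taxa <- unique(unlist(lapply(dataset$records, function(r) {
    c(
      r$subject$taxon$name, r$object$taxon$name,
      r$subject$taxon$classification_path, r$object$taxon$classification_path
    )
  })))
  maybe <- function(p, value) if (stats::runif(1) < p) value else NULL
  pick <- function(pool, k = 1) sample(pool, min(k, length(pool)))
  not_in_s <- maybe(0.3, pick(statuses, sample(1:2, 1)))
  in_s <- maybe(0.3, pick(setdiff(statuses, not_in_s), sample(1:2, 1)))
  not_in_o <- maybe(0.3, pick(statuses, sample(1:2, 1)))
  in_o <- maybe(0.3, pick(setdiff(statuses, not_in_o), sample(1:2, 1)))
  query_criteria(
    taxon_name = maybe(0.4, pick(taxa)),
    taxon_side = sample(c("either", "subject", "object"), 1),
    interaction_type = maybe(0.5, pick(types)),
    expand_hierarchy = stats::runif(1) < 0.7,
    match_inverse = stats::runif(1) < 0.7,
    subject_status_in = in_s,
    subject_status_not_in = not_in_s,
    object_status_in = in_o,
    object_status_not_in = not_in_o,
    interaction_status_in = maybe(0.3, pick(istatuses, sample(1:2, 1))),
    importance_in = maybe(0.2, pick(importances, sample(1:2, 1))),
    locality_name_contains = maybe(0.2, sample(c("San", "London", "Forest"), 1))
  )
}

record_uuids <- function(records) {
  vapply(records, function(r) r$uuid, character(1))
}

# a small hand-built valid record for mutation tests
valid_louse_record <- function(vocabs = default_vocabularies()) {
  create_record(
    subject = organism_role(
      taxon_concept("Columbicola columbae",
        classification_path = c(
          "Animalia", "Arthropoda", "Insecta",
          "Phthiraptera", "Columbicola columbae"
        )
      ),
      establishment_status = "Native", organism_part = "wings"
    ),
    object = organism_role("Columba livia", "Native"),
    interaction_type = "ectoparasite of",
    vocabularies = vocabs,
    interaction_status = "Interaction recorded in the wild",
    evidence = evidence_source("specimen", "NHMUK 0012345"),
    locality = locality("Richmond Park, London", 51.4428, -0.2674)
  )
}
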