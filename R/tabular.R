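#' Delimited-text input and output for interaction datasets
#'
#' Datasets are exchanged as CSV/TSV with a header row.  A declarative
#' column mapping ties record field paths (e.g. `subject.taxon.name`) to
#' source columns, so arbitrary host-association tables can be imported
#' without reshaping them first.  Incoming UUIDs are preserved verbatim
#' — identifiers must survive aggregation — and rows without one receive
#' a fresh random UUID.
#'
#' @name tabular_io
NULL

# every mappable record field path, in canonical serialisation order
FIELD_PATHS <- c(
  "uuid",
  "subject.taxon.name", "subject.taxon.rank",
  "subject.taxon.classification_path", "subject.taxon.external_id",
  "subject.establishment_status", "subject.organism_part",
  "interaction_type", "interaction_status", "importance",
  "object.taxon.name", "object.taxon.rank",
  "object.taxon.classification_path", "object.taxon.external_id",
  "object.establishment_status", "object.organism_part",
  "locality.name", "locality.latitude", "locality.longitude",
  "evidence"
)

REQUIRED_PATHS <- c("subject.taxon.name", "object.taxon.name", "interaction_type")

# canonical column names: field paths with dots swapped for underscores
CANONICAL_COLUMNS <- gsub(".", "_", FIELD_PATHS, fixed = TRUE)

#' Declare how source columns map onto record fields
#'
#' @param assignments Named character vector: names are record field
#'   paths (see Details), values are source column names.
#' @param constants Named list: field paths given a fixed value applied
#'   to every row.
#'
#' @details Field paths are dotted: `subject.taxon.name`,
#' `subject.establishment_status`, `interaction_type`,
#' `locality.latitude`, `evidence`, and so on.  The three paths
#' `subject.taxon.name`, `object.taxon.name` and `interaction_type` must
#' each be covered by an assignment or a constant; no path may be both.
#'
#' @return A `column_mapping`.
#' @export
column_mapping <- function(assignments = character(0), constants = list()) {
  assignments <- unlist(assignments)
  bad <- setdiff(c(names(assignments), names(constants)), FIELD_PATHS)
  if (length(bad) > 0) {
    abort(sprintf("unknown field path(s): %s", paste(bad, collapse = ", ")))
  }
  both <- intersect(names(assignments), names(constants))
  if (length(both) > 0) {
    abort(sprintf(
      "field path(s) both assigned and constant: %s",
      paste(both, collapse = ", ")
    ))
  }
  missing <- setdiff(REQUIRED_PATHS, c(names(assignments), names(constants)))
  if (length(missing) > 0) {
    abort(sprintf(
      "required field path(s) not covered: %s",
      paste(missing, collapse = ", ")
    ))
  }
  structure(
    list(assignments = assignments, constants = constants),
    class = "column_mapping"
  )
}

#' The canonical column mapping
#'
#' Maps every field path to the canonical column written by
#' [write_dataset()] (field path with dots replaced by underscores).
#'
#' @return A `column_mapping`.
#' @export
canonical_mapping <- function() {
  m <- stats::setNames(CANONICAL_COLUMNS, FIELD_PATHS)
  column_mapping(assignments = m)
}

#' Read a column mapping from a config file
#'
#' One `key = value` pair per line: key is a field path, value a source
#' column name, or `!literal` for a constant applied to every row.
#' Blank lines and `#` comments are ignored.
#'
#' @param path Config file path.
#' @return A `column_mapping`.
#' @export
read_mapping <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  assignments <- character(0)
  constants <- list()
  for (ln in lines) {
    parts <- stringr::str_split_fixed(ln, "=", 2)
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    if (startsWith(val, "!")) {
      constants[[key]] <- substring(val, 2)
    } else {
      assignments[key] <- val
    }
  }
  column_mapping(assignments, constants)
}

# ---- compound-field escaping -------------------------------------------
# classification paths are pipe-joined; evidence items are
# kind:citation[:identifier] joined by ';'.  Delimiters inside values are
# escaped by doubling.

esc <- function(x, ch) gsub(ch, paste0(ch, ch), x, fixed = TRUE)

split_escaped <- function(x, ch) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  placeholder <- "\x01"
  x <- gsub(paste0(ch, ch), placeholder, x, fixed = TRUE)
  parts <- strsplit(x, ch, fixed = TRUE)[[1]]
  gsub(placeholder, ch, parts, fixed = TRUE)
}

serialize_path <- function(path) {
  if (length(path) == 0) return("")
  paste(esc(path, "|"), collapse = "|")
}

parse_path <- function(x) split_escaped(x, "|")

serialize_evidence <- function(evidence) {
  if (length(evidence) == 0) return("")
  items <- vapply(evidence, function(ev) {
    fields <- c(ev$kind, ev$citation)
    if (!is.na(ev$identifier)) fields <- c(fields, ev$identifier)
    paste(esc(esc(fields, ";"), ":"), collapse = ":")
  }, character(1))
  paste(items, collapse = ";")
}

parse_evidence <- function(x) {
  items <- split_escaped(x, ";")
  lapply(items, function(item) {
    fields <- split_escaped(item, ":")
    evidence_source(
      kind = fields[1],
      citation = if (length(fields) >= 2) fields[2] else NA_character_,
      identifier = if (length(fields) >= 3) fields[3] else NA_character_
    )
  })
}

format_coord <- function(x) {
  if (is.na(x)) "" else format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

# one record -> named character vector over CANONICAL_COLUMNS
record_to_row <- function(record) {
  role_fields <- function(role) {
    c(
      role$taxon$name,
      na_to_empty(role$taxon$rank),
      serialize_path(role$taxon$classification_path),
      na_to_empty(role$taxon$external_id),
      role$establishment_status,
      na_to_empty(role$organism_part)
    )
  }
  loc <- record$locality
  vals <- c(
    record$uuid,
    role_fields(record$subject),
    record$interaction_type,
    record$interaction_status,
    na_to_empty(record$importance),
    role_fields(record$object),
    if (is.null(loc)) c("", "", "") else {
      c(na_to_empty(loc$name), format_coord(loc$latitude), format_coord(loc$longitude))
    },
    serialize_evidence(record$evidence)
  )
  stats::setNames(vals, CANONICAL_COLUMNS)
}

# named list of raw field-path values (character or NA) -> record
fields_to_record <- function(f) {
  get <- function(path) {
    v <- f[[path]]
    if (is.null(v)) NA_character_ else empty_to_na(v)
  }
  role <- function(side) {
    organism_role(
      taxon = taxon_concept(
        name = na_to_empty(get(paste0(side, ".taxon.name"))),
        rank = get(paste0(side, ".taxon.rank")),
        classification_path = parse_path(get(paste0(side, ".taxon.classification_path"))),
        external_id = get(paste0(side, ".taxon.external_id"))
      ),
      establishment_status = get(paste0(side, ".establishment_status")) %|na|% "unknown",
      organism_part = get(paste0(side, ".organism_part"))
    )
  }
  lat <- get("locality.latitude")
  lon <- get("locality.longitude")
  loc_name <- get("locality.name")
  loc <- if (is.na(lat) && is.na(lon) && is.na(loc_name)) {
    NULL
  } else {
    locality(
      name = loc_name,
      latitude = suppressWarnings(as.numeric(lat)),
      longitude = suppressWarnings(as.numeric(lon))
    )
  }
  new_interaction_record(
    uuid = get("uuid"),
    subject = role("subject"),
    object = role("object"),
    interaction_type = na_to_empty(get("interaction_type")),
    interaction_status = get("interaction_status") %|na|% "unknown",
    importance = get("importance"),
    evidence = parse_evidence(na_to_empty(get("evidence"))),
    locality = loc
  )
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a dataset from delimited text
#'
#' One record is built per data row, in file order.  Rows carrying a
#' UUID keep it verbatim; others receive fresh random UUIDs.  In strict
#' mode the first violation aborts with its row number; otherwise
#' offending rows are skipped and all violations collected in the import
#' report.
#'
#' @param path CSV/TSV file with a header row.
#' @param mapping A [column_mapping()]; defaults to the canonical one.
#' @param vocabularies Vocabulary set records are validated against.
#' @param strict Abort on the first invalid row instead of skipping it.
#' @param delim Field delimiter; inferred from the extension when `NULL`
#'   (`.csv` comma, otherwise tab).
#' @return A list with elements `dataset` (an `interaction_dataset`) and
#'   `report` (an `import_report` counting rows read, records created,
#'   rows skipped, and violations by row and field).
#' @export
read_dataset <- function(path, mapping = canonical_mapping(),
                         vocabularies = default_vocabularies(),
                         strict = FALSE, delim = NULL) {
  stopifnot(inherits(mapping, "column_mapping"))
  delim <- delim_for(path, delim)
  raw <- readr::read_delim(path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(unname(mapping$assignments), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "mapped column(s) absent from '%s': %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }

  violations <- cbind(tibble(row = integer(0)), no_violations())
  records <- list()
  seen <- character(0)
  skipped <- 0L

  for (i in seq_len(nrow(raw))) {
    f <- lapply(
      stats::setNames(nm = names(mapping$assignments)),
      function(p) raw[[mapping$assignments[[p]]]][i]
    )
    for (p in names(mapping$constants)) f[[p]] <- mapping$constants[[p]]
    rec <- fields_to_record(f)

    row_viol <- no_violations()
    if (is.na(rec$uuid)) {
      rec$uuid <- new_uuid()
    } else if (rec$uuid %in% seen) {
      row_viol <- rbind(row_viol, violation(
        "uuid", rec$uuid, "duplicate uuid within the imported file"
      ))
    }
    # canonicalise resolvable labels, then validate
    rec <- canonicalize_record(rec, vocabularies)
    row_viol <- rbind(row_viol, validate_record(rec, vocabularies))

    if (nrow(row_viol) > 0) {
      if (strict) {
        abort(sprintf(
          "row %d: %s '%s' (%s)", i, row_viol$field[1],
          na_to_empty(row_viol$value[1]), row_viol$rule[1]
        ))
      }
      skipped <- skipped + 1L
      violations <- rbind(violations, cbind(tibble(row = i), row_viol))
    } else {
      seen <- c(seen, rec$uuid)
      records <- c(records, list(rec))
    }
  }

  dataset <- new_dataset(
    records = records, vocabularies = vocabularies,
    metadata = list(source = path)
  )
  report <- structure(
    list(
      rows_read = nrow(raw),
      records_created = length(records),
      rows_skipped = skipped,
      violations = as_tibble(violations)
    ),
    class = "import_report"
  )
  list(dataset = dataset, report = report)
}

# case-fix labels that resolve; leave unresolvable values verbatim so the
# validator can report them
canonicalize_record <- function(rec, vocabularies) {
  fix <- function(x, labels) {
    if (is.na(x) || identical(tolower(x), "unknown")) return(x)
    hit <- canonical_label(x, labels)
    if (is.na(hit)) x else hit
  }
  rec$subject$establishment_status <- fix(
    rec$subject$establishment_status, vocabularies$organism_status$label
  )
  rec$object$establishment_status <- fix(
    rec$object$establishment_status, vocabularies$organism_status$label
  )
  rec$interaction_type <- fix(
    rec$interaction_type, vocabularies$interaction_types$label
  )
  rec$interaction_status <- fix(
    rec$interaction_status, vocabularies$interaction_status$label
  )
  rec$importance <- fix(rec$importance, vocabularies$importance$label)
  rec
}

#' @export
print.import_report <- function(x, ...) {
  cat(sprintf(
    "<import_report> rows read: %d; records created: %d; rows skipped: %d\n",
    x$rows_read, x$records_created, x$rows_skipped
  ))
  if (nrow(x$violations) > 0) {
    tab <- table(x$violations$field)
    cat(
      "violations by field:",
      paste(names(tab), tab, sep = "=", collapse = "; "), "\n"
    )
  }
  invisible(x)
}

quote_csv <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Write a dataset as delimited text
#'
#' Deterministic, byte-stable output: fixed canonical column order,
#' canonical label casing, UTF-8 with LF line endings.  Writing, reading
#' with the canonical mapping and writing again reproduces the file byte
#' for byte, UUIDs and record order included.  In CSV, free-text fields
#' containing the delimiter, quotes or newlines are quoted; in TSV,
#' embedded tabs and newlines are replaced by single spaces (with a
#' warning), since the dialect has no quoting.
#'
#' @param dataset An `interaction_dataset`; must validate cleanly.
#' @param path Output path; extension selects the dialect unless `delim`
#'   is given.
#' @param delim Field delimiter override.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, delim = NULL) {
  viol <- validate_dataset(dataset)
  if (nrow(viol) > 0) {
    abort(sprintf(
      "dataset does not validate: %d violation(s), first on record %s field %s",
      nrow(viol), viol$uuid[1], viol$field[1]
    ))
  }
  delim <- delim_for(path, delim)
  rows <- lapply(dataset$records, record_to_row)
  mat <- do.call(rbind, c(list(matrix(
    character(0),
    ncol = length(CANONICAL_COLUMNS)
  )), rows))
  if (identical(delim, "\t")) {
    had_bad <- any(grepl("[\t\n\r]", mat))
    mat[] <- gsub("[\t\n\r]+", " ", mat)
    if (had_bad) {
      warning("embedded tabs/newlines replaced by spaces in TSV output")
    }
  } else {
    mat[] <- quote_csv(mat)
  }
  body <- if (nrow(mat) == 0) {
    character(0)
  } else {
    apply(mat, 1, paste, collapse = delim)
  }
  header <- paste(CANONICAL_COLUMNS, collapse = delim)
  lines <- c(header, if (length(body) > 0) body)
  write_lines_lf(lines, path)
  invisible(path)
}
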