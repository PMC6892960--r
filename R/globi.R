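#' GloBI harvest file
#'
#' Global Biotic Interactions (GloBI) aggregates species-interaction
#' datasets harvested from distributed sources as simple tab-separated
#' text files.  [export_globi()] emits one such file for a dataset —
#' conventionally named `interactions.txt` — and [check_globi_file()]
#' verifies the contract on any file claiming to follow it.
#'
#' The column schema is this package's own contract, chosen to carry
#' every modelled field under GloBI-style column names so mapping onto a
#' GloBI ingestion template is a rename-only step.
#'
#' @name globi_io
NULL

GLOBI_COLUMNS <- c(
  "sourceOccurrenceId", "sourceTaxonName", "sourceBodyPartName",
  "sourceEstablishmentMeans", "interactionTypeName", "interactionTypeId",
  "targetTaxonName", "targetBodyPartName", "targetEstablishmentMeans",
  "interactionRecordType", "importance", "localityName",
  "decimalLatitude", "decimalLongitude", "referenceCitation",
  "evidenceKind"
)

globi_sanitize <- function(x) gsub("[\t\n\r]+", " ", x)

globi_row <- function(record, vocab) {
  uri <- tryCatch(
    term_uri(vocab, record$interaction_type),
    error = function(e) NA_character_
  )
  if (is.na(uri)) {
    abort(sprintf(
      "record %s: interaction type '%s' has no URI in the vocabulary",
      record$uuid, record$interaction_type
    ))
  }
  refs <- Filter(function(ev) ev$kind == "reference", record$evidence)
  first_ref <- if (length(refs) > 0) refs[[1]]$citation else ""
  kinds <- vapply(record$evidence, function(ev) ev$kind, character(1))
  loc <- record$locality
  vals <- c(
    record$uuid,
    record$subject$taxon$name,
    na_to_empty(record$subject$organism_part),
    record$subject$establishment_status,
    record$interaction_type,
    uri,
    record$object$taxon$name,
    na_to_empty(record$object$organism_part),
    record$object$establishment_status,
    record$interaction_status,
    na_to_empty(record$importance),
    if (is.null(loc)) "" else na_to_empty(loc$name),
    if (is.null(loc)) "" else format_coord(loc$latitude),
    if (is.null(loc)) "" else format_coord(loc$longitude),
    first_ref,
    paste(kinds, collapse = ",")
  )
  paste(globi_sanitize(vals), collapse = "\t")
}

#' Export a dataset as a GloBI-harvestable interactions file
#'
#' Writes UTF-8, LF-terminated, tab-separated text: exactly one header
#' row, then one row per record in dataset order.  Absent values are
#' empty fields; tabs and newlines inside values are replaced by single
#' spaces.  The export is byte-deterministic for a given dataset.  Only
#' the first reference-kind evidence item is exported to
#' `referenceCitation`; all evidence kinds are summarised as a
#' comma-joined list in `evidenceKind`, keeping the file
#' one-row-per-interaction.
#'
#' @param dataset An `interaction_dataset`; must validate cleanly and
#'   every interaction type must carry a URI.
#' @param path Output path (conventionally `interactions.txt`).
#' @return `path`, invisibly.
#' @export
export_globi <- function(dataset, path) {
  viol <- validate_dataset(dataset)
  if (nrow(viol) > 0) {
    abort(sprintf(
      "dataset does not validate: %d violation(s), first on record %s",
      nrow(viol), viol$uuid[1]
    ))
  }
  vocab <- dataset$vocabularies$interaction_types
  body <- vapply(dataset$records, globi_row, character(1), vocab = vocab)
  lines <- c(paste(GLOBI_COLUMNS, collapse = "\t"), body)
  write_lines_lf(lines, path)
  invisible(path)
}

globi_rule <- function(rule, pass, lines = integer(0)) {
  list(rule = rule, pass = pass, lines = lines)
}

#' Check a file against the GloBI harvest contract
#'
#' Verifies that the header exactly matches the canonical column list,
#' that every line has a constant field count, that the bytes decode as
#' UTF-8, that no field contains a raw tab or newline, and that
#' `sourceTaxonName`, `targetTaxonName` and `interactionTypeName` are
#' non-empty on every row.  Findings are reported, never raised.
#'
#' @param path Path to a candidate interactions file.
#' @return A `globi_check_report`: per-rule pass/fail with offending
#'   line numbers, and an overall `all_pass` flag.
#' @export
check_globi_file <- function(path) {
  stopifnot(file.exists(path))
  raw <- readBin(path, "raw", file.info(path)$size)
  txt <- rawToChar(raw)
  utf8_ok <- !is.na(iconv(txt, "UTF-8", "UTF-8"))
  rules <- list(globi_rule("utf8_decodable", utf8_ok))
  # strsplit on "\n" drops the trailing newline itself, so a correctly
  # LF-terminated file yields exactly header + data lines
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]

  header_fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rules <- c(rules, list(globi_rule(
    "header_matches_canonical_columns",
    identical(header_fields, GLOBI_COLUMNS),
    if (!identical(header_fields, GLOBI_COLUMNS)) 1L else integer(0)
  )))

  # strsplit drops trailing empty fields, so count tabs instead
  n_fields <- stringr::str_count(lines, stringr::fixed("\t")) + 1L
  bad_count <- which(n_fields != length(GLOBI_COLUMNS))
  rules <- c(rules, list(globi_rule(
    "constant_field_count", length(bad_count) == 0, bad_count
  )))

  bad_cr <- which(grepl("\r", lines, fixed = TRUE))
  rules <- c(rules, list(globi_rule(
    "no_raw_carriage_returns", length(bad_cr) == 0, bad_cr
  )))

  data_lines <- if (length(lines) > 1) lines[-1] else character(0)
  required_ok <- rep(TRUE, length(data_lines))
  for (i in seq_along(data_lines)) {
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    need <- match(
      c("sourceTaxonName", "targetTaxonName", "interactionTypeName"),
      GLOBI_COLUMNS
    )
    vals <- fields[need]
    required_ok[i] <- length(fields) >= max(need) &&
      all(!is.na(vals) & nzchar(vals))
  }
  rules <- c(rules, list(globi_rule(
    "required_names_non_empty", all(required_ok), which(!required_ok) + 1L
  )))

  structure(
    list(
      rules = rules,
      all_pass = all(vapply(rules, function(r) r$pass, logical(1))),
      n_lines = length(lines)
    ),
    class = "globi_check_report"
  )
}

#' @export
print.globi_check_report <- function(x, ...) {
  cat(sprintf(
    "<globi_check_report> %d line(s); %s\n",
    x$n_lines, if (x$all_pass) "all rules pass" else "FAILURES:"
  ))
  for (r in x$rules) {
    if (!r$pass) {
      cat(sprintf(
        "  %s: FAIL (line %s)\n", r$rule,
        paste(head(r$lines, 5), collapse = ", ")
      ))
    }
  }
  invisible(x)
}
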