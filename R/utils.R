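#' @importFrom rlang %||% abort
#' @importFrom tibble tibble as_tibble
#' @importFrom utils head
NULL

# Fixed namespace for name-based (version-5) UUIDs used by the fixture
# generator; arbitrary but constant so fixtures are reproducible.
UUID_NAMESPACE <- "3f2c7d0e-5a41-4d9b-8b6a-2e9c1f7a8d54"

UUID_REGEX <- "^[0-9a-fA-F]{8}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{12}$"

#' Generate a random (version-4) UUID
#'
#' Used for newly created records; importers never call this for rows that
#' already carry an identifier.
#'
#' @return A UUID string.
#' @export
new_uuid <- function() {
  uuid::UUIDgenerate(use.time = FALSE)
}

#' Derive a name-based (version-5) UUID from content
#'
#' Deterministic: the same components always yield the same UUID.  The
#' fixture generator uses these so generated datasets are byte-reproducible
#' across runs and machines.
#'
#' @param ... Character components hashed into the name.
#' @return A UUID string.
#' @export
content_uuid <- function(...) {
  uuid::UUIDfromName(UUID_NAMESPACE, paste(c(...), collapse = "/"))
}

#' Test whether a string is a syntactically valid UUID
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_valid_uuid <- function(x) {
  !is.na(x) & grepl(UUID_REGEX, x)
}

# Case-insensitive label resolution against a vocabulary's canonical labels.
# Returns the canonical (table-cased) label, or NA when absent.
canonical_label <- function(x, labels) {
  if (length(x) == 0) return(character(0))
  idx <- match(tolower(trimws(x)), tolower(labels))
  out <- labels[idx]
  out
}

resolves_in <- function(x, labels) {
  !is.na(canonical_label(x, labels))
}

# empty-string-as-missing conventions used by the delimited readers/writers
na_to_empty <- function(x) ifelse(is.na(x), "", x)
empty_to_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)

violation <- function(field, value, rule) {
  tibble(
    field = as.character(field),
    value = ifelse(is.na(value), NA_character_, as.character(value)),
    rule = as.character(rule)
  )
}

no_violations <- function() {
  tibble(field = character(), value = character(), rule = character())
}

# Write lines with LF endings and UTF-8 bytes regardless of platform.
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
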