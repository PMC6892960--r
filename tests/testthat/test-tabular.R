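vocabs <- default_vocabularies()

write_louse_file <- function(path, rows) {
  writeLines(c("louse\thost\trelation\tpart", rows), path)
}

louse_mapping <- column_mapping(
  assignments = c(
    "subject.taxon.name" = "louse",
    "object.taxon.name" = "host",
    "interaction_type" = "relation",
    "subject.organism_part" = "part"
  ),
  constants = list(
    "interaction_status" = "Interaction recorded in the wild",
    "evidence" = "reference:Clay (1949) Some problems in the evolution of a group of ectoparasites."
  )
)

test_that("column mappings enforce coverage and disjointness", {
  expect_error(
    column_mapping(c("subject.taxon.name" = "a")),
    "required field path"
  )
  expect_error(
    column_mapping(c("subject.wing_length" = "a")),
    "unknown field path"
  )
  expect_error(
    column_mapping(
      c(
        "subject.taxon.name" = "a", "object.taxon.name" = "b",
        "interaction_type" = "c"
      ),
      constants = list("interaction_type" = "eats")
    ),
    "both assigned and constant"
  )
})

test_that("a clean import creates one record per row in file order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_louse_file(f, c(
    "Columbicola columbae\tColumba livia\tectoparasite of\twings",
    "Menacanthus stramineus\tGallus gallus\tectoparasite of\t",
    "Trichodectes canis\tCanis lupus\tectoparasite of\trump"
  ))
  res <- read_dataset(f, louse_mapping, vocabs, strict = TRUE)
  expect_equal(length(res$dataset), 3)
  expect_equal(res$report$rows_skipped, 0)
  expect_equal(res$report$rows_read, 3)
  expect_equal(res$dataset$records[[1]]$subject$organism_part, "wings")
  expect_equal(res$dataset$records[[1]]$subject$taxon$name, "Columbicola columbae")
  expect_equal(res$dataset$records[[1]]$evidence[[1]]$kind, "reference")
  expect_true(all(is_valid_uuid(record_uuids(res$dataset$records))))
})

test_that("invalid rows are skipped and reported in lenient mode, fatal in strict", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_louse_file(f, c(
    "Columbicola columbae\tColumba livia\tectoparasite of\t",
    "Menacanthus stramineus\tGallus gallus\tectoparasiet of\t", # misspelled
    "Trichodectes canis\tCanis lupus\tectoparasite of\t"
  ))
  res <- read_dataset(f, louse_mapping, vocabs, strict = FALSE)
  expect_equal(length(res$dataset), 2)
  expect_equal(res$report$rows_skipped, 1)
  expect_equal(res$report$violations$row, 2)
  expect_equal(res$report$violations$field, "interaction_type")

  expect_error(
    read_dataset(f, louse_mapping, vocabs, strict = TRUE),
    "row 2"
  )
})

test_that("a missing mapped column is an error before any row is read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("louse\thost", "a\tb"), f)
  expect_error(
    read_dataset(f, louse_mapping, vocabs),
    "mapped column\\(s\\) absent.*relation"
  )
})

test_that("incoming UUIDs are preserved verbatim and duplicates handled per mode", {
  uid <- "11111111-2222-4333-8444-555555555555"
  m <- column_mapping(c(
    "uuid" = "id",
    "subject.taxon.name" = "a", "object.taxon.name" = "b",
    "interaction_type" = "rel"
  ))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\ta\tb\trel",
    paste(uid, "x", "y", "eats", sep = "\t"),
    paste(uid, "p", "q", "eats", sep = "\t")
  ), f)
  res <- read_dataset(f, m, vocabs, strict = FALSE)
  expect_equal(length(res$dataset), 1)
  expect_equal(res$dataset$records[[1]]$uuid, uid)
  expect_equal(res$report$violations$rule, "duplicate uuid within the imported file")
  expect_error(read_dataset(f, m, vocabs, strict = TRUE), "duplicate uuid")
})

test_that("write -> read -> write is byte-identical, TSV and CSV", {
  fx <- generate_fixture(fixture_spec(11, 60, "mixed"), vocabs)
  for (ext in c(".tsv", ".csv")) {
    f1 <- withr::local_tempfile(fileext = ext)
    f2 <- withr::local_tempfile(fileext = ext)
    write_dataset(fx$dataset, f1)
    rt <- read_dataset(f1, vocabularies = vocabs)
    expect_equal(rt$report$rows_skipped, 0)
    write_dataset(rt$dataset, f2)
    expect_identical(
      readBin(f1, "raw", file.size(f1)),
      readBin(f2, "raw", file.size(f2))
    )
    # field-by-field equality, not just bytes
    expect_equal(rt$dataset$records, fx$dataset$records)
  }
})

test_that("an empty dataset writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(new_dataset(vocabularies = vocabs), f)
  expect_equal(length(readLines(f)), 1)
  rt <- read_dataset(f, vocabularies = vocabs)
  expect_equal(length(rt$dataset), 0)
})

test_that("free text with delimiters survives CSV and is sanitised in TSV", {
  r <- create_record(
    organism_role(
      taxon_concept("Aphis fabae",
        classification_path = c("Animalia", "Arthropoda|Insecta", "Aphis fabae")
      ),
      "Native",
      organism_part = "leaf, underside"
    ),
    organism_role("Vicia faba", "Managed"),
    "eats",
    vocabularies = vocabs,
    evidence = evidence_source("reference", "Smith; Jones (1901): notes")
  )
  ds <- new_dataset(list(r), vocabularies = vocabs)

  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  rt <- read_dataset(f, vocabularies = vocabs)
  expect_equal(rt$dataset$records, ds$records)

  r2 <- r
  r2$subject$organism_part <- "leaf\tunderside"
  ds2 <- new_dataset(list(r2), vocabularies = vocabs)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  expect_warning(write_dataset(ds2, f2), "replaced by spaces")
  rt2 <- read_dataset(f2, vocabularies = vocabs)
  expect_equal(rt2$dataset$records[[1]]$subject$organism_part, "leaf underside")
})

test_that("import count matches an independent row-validity oracle on a large file", {
  withr::local_seed(77)
  fx <- generate_fixture(fixture_spec(13, 500, "mixed"), vocabs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(fx$dataset, f)
  # corrupt a known subset of rows with out-of-vocabulary values
  lines <- readLines(f)
  bad_rows <- sort(sample(2:length(lines), 40))
  for (i in bad_rows) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields[6] <- "Alien" # subject_establishment_status
    lines[i] <- paste(fields, collapse = "\t")
  }
  writeLines(lines, f)
  res <- read_dataset(f, vocabularies = vocabs)
  # oracle: validate each raw row independently against the vocabulary
  raw_ok <- vapply(2:length(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields[6] %in% c(load_status_vocabulary("table1")$label, "unknown")
  }, logical(1))
  expect_equal(res$report$records_created, sum(raw_ok))
  expect_equal(res$report$rows_skipped, length(bad_rows))
})

test_that("mapping config files parse assignments and constants", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# louse table",
    "subject.taxon.name = louse",
    "object.taxon.name = host",
    "interaction_type = !ectoparasite of",
    "subject.organism_part = part"
  ), f)
  m <- read_mapping(f)
  expect_equal(unname(m$assignments["subject.taxon.name"]), "louse")
  expect_equal(m$constants$interaction_type, "ectoparasite of")
})
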