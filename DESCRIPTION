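Package: ecointeractions
Title: Structured Species-Interaction Records with Controlled
    Vocabularies and GloBI Export
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A data model and command-line toolkit for documented
    ecological interactions between pairs of organisms.  Records carry a
    persistent UUID, evidence (references, specimens, observations), a
    locality, establishment statuses aligned to the Darwin Core
    establishmentMeans vocabulary, a wild/captive interaction status, an
    importance-to-humans value, and a typed relation drawn from a
    hierarchical vocabulary of Relations Ontology terms with inverse
    pairs ("eats"/"eaten by").  Datasets are read and written as
    delimited text with a declarative column mapping, queried with
    faceted filters that expand the term hierarchy and match inverse
    directions, and exported as the tab-separated interactions file
    harvested by Global Biotic Interactions (GloBI).  Seeded synthetic
    fixtures emulating lepidopteran/phasmid host-plant records and
    louse-host records make the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    uuid,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
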