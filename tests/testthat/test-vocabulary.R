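test_that("packaged status vocabularies load with the expected entries", {
  t1 <- load_status_vocabulary("table1")
  expect_equal(nrow(t1), 6)
  expect_equal(t1$label[1], "Native")
  expect_equal(
    t1$description[1],
    "The organism either evolved in this region or arrived by non-anthropogenic means."
  )
  expect_setequal(
    t1$label,
    c("Native", "Naturalised", "Introduced", "Invasive", "Captivity", "Managed")
  )

  t2 <- load_status_vocabulary("table2")
  expect_equal(nrow(t2), 4)
  expect_equal(t2$label[1], "Interaction recorded in the wild")
  expect_equal(t2$description[1], "")

  t3 <- load_status_vocabulary("table3")
  expect_true("Economic (pest control)" %in% t3$label)
  expect_equal(
    t3$description[t3$label == "Economic (pest control)"],
    "The interaction helps to control a pest species"
  )

  expect_error(load_status_vocabulary("table9"), "unknown built-in")
})

test_that("duplicate labels in a status vocabulary are a parse error with a line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tdescription", "Native\tx", "native\ty"), f)
  expect_error(load_status_vocabulary(f), "duplicate label 'native' at line 3")
})

test_that("the packaged interaction vocabulary has the documented structure", {
  ro <- load_interaction_vocabulary("ro-core")
  expect_equal(inverse_of(ro, "eats"), "eaten by")
  expect_equal(
    ro$parent_label[ro$label == "ectoparasite of"], "parasite of"
  )
  expect_true(all(
    c("parasite of", "ectoparasite of") %in% descendants(ro, "parasite of")
  ))
  # a symmetric root relation is its own inverse
  expect_equal(inverse_of(ro, "interacts with"), "interacts with")
  # lookups are case-insensitive, output canonical
  expect_equal(inverse_of(ro, "EATS"), "eaten by")
  expect_error(inverse_of(ro, "devours"), "unknown interaction-type label")
  expect_error(descendants(ro, "devours"), "unknown interaction-type label")
})

test_that("inverse_of is an involution on every packaged term", {
  ro <- load_interaction_vocabulary("ro-core")
  for (lbl in ro$label) {
    expect_equal(inverse_of(ro, inverse_of(ro, lbl)), lbl)
  }
})

test_that("descendants of a leaf term is the term itself", {
  ro <- load_interaction_vocabulary("ro-core")
  expect_equal(descendants(ro, "ectoparasite of"), "ectoparasite of")
})

test_that("broken vocabularies are rejected at load", {
  # X's inverse is Y but Y's inverse is Z
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "label\turi\tinverse_label\tinverse_uri\tparent_label",
    "X\tu:x\tY\tu:y\t",
    "Y\tu:y\tZ\tu:z\t",
    "Z\tu:z\tY\tu:y\t"
  ), f)
  expect_error(load_interaction_vocabulary(f), "asymmetric inverse pair")

  # parent cycle
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "label\turi\tinverse_label\tinverse_uri\tparent_label",
    "A\tu:a\tA\tu:a\tB",
    "B\tu:b\tB\tu:b\tA"
  ), f2)
  expect_error(load_interaction_vocabulary(f2), "cycle through: A, B")

  # dangling parent
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "label\turi\tinverse_label\tinverse_uri\tparent_label",
    "A\tu:a\tA\tu:a\tnowhere"
  ), f3)
  expect_error(load_interaction_vocabulary(f3), "unresolvable parent")
})

test_that("add_term extends the hierarchy and maintains symmetry", {
  ro <- load_interaction_vocabulary("ro-core")
  base <- ro[!(ro$label %in% c("endoparasite of", "has endoparasite")), ]
  base <- load_interaction_vocabulary(
    write_interaction_vocabulary(
      structure(base, class = class(ro)),
      withr::local_tempfile(fileext = ".tsv")
    )
  )
  v2 <- add_term(base,
    interaction_type_term(
      "endoparasite of", "u:endo", "has endoparasite", "u:hasendo",
      parent_label = "parasite of"
    ),
    inverse = interaction_type_term(
      "has endoparasite", "u:hasendo", "endoparasite of", "u:endo",
      parent_label = "parasitized by"
    )
  )
  expect_true("endoparasite of" %in% descendants(v2, "parasite of"))
  expect_equal(inverse_of(v2, "endoparasite of"), "has endoparasite")
  expect_equal(inverse_of(v2, "has endoparasite"), "endoparasite of")

  expect_error(
    add_term(base, interaction_type_term("selfie", "u:s", "selfie", "u:s",
      parent_label = "selfie"
    )),
    "own parent"
  )
  expect_error(
    add_term(base, interaction_type_term("EATS", "u:e2", "EATS", "u:e2")),
    "already exists"
  )
  expect_error(
    add_term(base, interaction_type_term(
      "novel", "u:n", "no such inverse", "u:nsi"
    )),
    "unresolvable inverse"
  )
})

test_that("invariants survive random add_term sequences", {
  withr::local_seed(101)
  ro <- load_interaction_vocabulary("ro-core")
  v <- ro
  for (k in 1:25) {
    lbl <- sprintf("added %02d", k)
    inv_lbl <- sprintf("added %02d rev", k)
    parent <- if (stats::runif(1) < 0.5) sample(v$label, 1) else NA_character_
    v <- add_term(v,
      interaction_type_term(lbl, paste0("u:", k), inv_lbl, paste0("u:", k, "r"),
        parent_label = parent
      ),
      inverse = interaction_type_term(
        inv_lbl, paste0("u:", k, "r"), lbl, paste0("u:", k)
      )
    )
    # symmetry and involution after every addition
    for (t in c(lbl, inv_lbl, "eats")) {
      expect_equal(inverse_of(v, inverse_of(v, t)), t)
    }
  }
  expect_equal(nrow(v), nrow(ro) + 50)
})

test_that("vocabularies round-trip through their TSV serialisation", {
  ro <- load_interaction_vocabulary("ro-core")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_vocabulary(ro, f)
  expect_equal(load_interaction_vocabulary(f), ro)

  for (b in c("table1", "table2", "table3")) {
    sv <- load_status_vocabulary(b)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_status_vocabulary(sv, f2)
    rt <- load_status_vocabulary(f2, name = attr(sv, "vocab_name"))
    expect_equal(as.data.frame(rt), as.data.frame(sv))
  }
})

test_that("descendants agrees with naive traversal on random forests", {
  withr::local_seed(202)
  for (rep in 1:20) {
    n <- sample(5:120, 1)
    f <- withr::local_tempfile(fileext = ".tsv")
    random_forest_tsv(n, f)
    v <- load_interaction_vocabulary(f)
    for (lbl in sample(v$label, min(n, 10))) {
      expect_setequal(descendants(v, lbl), oracle_descendants(v, lbl))
    }
  }
})

test_that("the packaged vocabulary passes the hierarchy/inverse lint", {
  ro <- load_interaction_vocabulary("ro-core")
  expect_length(lint_interaction_vocabulary(ro), 0)
  # a child whose inverse escapes the parent's inverse subtree is flagged
  v <- add_term(ro, interaction_type_term(
    "odd child", "u:odd", "odd child", "u:odd",
    parent_label = "parasite of"
  ))
  expect_length(lint_interaction_vocabulary(v), 1)
})
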