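---
title: "The interaction data model: vocabularies, retrieval semantics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The interaction data model: vocabularies, retrieval semantics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecointeractions)
```

## The record model and its assumptions

An `interaction_record` documents one typed interaction between two
organism roles. The model makes a small number of deliberate
assumptions:

* **One relation per record, either direction storable.** A
  louse-on-pigeon observation may arrive as "ectoparasite of" (louse
  subject) or "has ectoparasite" (pigeon subject), depending on the
  source's orientation. Rather than forcing a canonical direction at
  ingest, both are storable and retrieval compensates: with
  `match_inverse` on, `filter_records()` also accepts a record whose
  `reversed_view()` satisfies the criteria, evaluating role-specific
  criteria against the swapped roles. `reversed_view()` itself is an
  involution — applying it twice returns the original record field for
  field — which the test suite checks across whole generated datasets.
* **Per-record classification paths.** Host taxonomies differ between
  compilations (bird and mammal classifications used by different louse
  checklists disagree), so each role carries its own optional
  root-to-taxon path instead of the dataset owning one global tree.
  Taxon queries match the name or any path element, by exact string;
  name reconciliation and fuzzy matching are out of scope.
* **Verbatim organism parts.** Anatomy vocabularies exist (Uberon and
  relatives) but none fits every community, so parts are stored as
  free text exactly as the source gives them ("wings", "head and
  neck"), and validation never touches them.
* **The `"unknown"` sentinel.** The status vocabularies are closed
  lists with no null entry. Records awaiting curation still need to be
  representable, so both status fields accept the sentinel `"unknown"`,
  which also appears as its own facet value so curators can find
  unscored records.
* **Violations are data.** `validate_record()` returns a tibble of
  violations (field, value, rule) rather than raising, because a
  curator triaging an import wants all problems at once. Only
  operations that cannot proceed at all (an unresolvable interaction
  type at creation, a duplicate UUID within a dataset) raise errors.

## Vocabularies

Three closed status vocabularies ship with the package and load by
built-in name: organism establishment status (`"table1"`, six labels
aligned to Darwin Core `establishmentMeans`), wild/captive recording
context (`"table2"`, four labels), and importance to humans
(`"table3"`, six labels). They are stored as plain TSV so a community
can replace them with its own files; labels match case-insensitively on
input and are canonicalised to the packaged casing on output. The
packaged `"table2"` file reproduces its source table verbatim,
including the quirk that only the plain "recorded in captivity" entry
carries a description ("Used when the status of the specimens is
uncertain") while the other three entries have none; we preserve rather
than reinterpret it.

Interaction types form a fourth, hierarchical vocabulary. Each term
carries a label, an IRI, its inverse's label and IRI, and an optional
parent. The packaged `"ro-core"` set is hand-curated from the Relations
Ontology: a symmetric "interacts with" root, the eats/eaten by and
predation/pollination/host pairs, and a parasite-of subtree in which
"ectoparasite of" and "endoparasite of" sit under "parasite of" with
their inverses mirrored under "parasitized by". IRIs are treated as
opaque strings throughout — the code never parses or resolves them — so
swapping in a different ontology release is a data change, not a code
change. A TSV loader hook (`load_interaction_vocabulary()` on any
conforming file) supports exactly that.

Three structural invariants are enforced at every load and after every
`add_term()`: labels and IRIs unique, the parent graph an acyclic
forest (single parent, matching the taxonomy-style storage the model
targets; multi-parent DAGs are rejected), and inverse pairing exactly
symmetric. Because every term's inverse must resolve, a brand-new
inverse pair is added atomically via `add_term(vocab, term, inverse =
...)`. One relationship is deliberately *not* enforced: nothing forces
a child's inverse to descend from its parent's inverse. Curated
vocabularies normally mirror the hierarchy on both sides, but no formal
constraint requires it, so `lint_interaction_vocabulary()` reports such
asymmetries as warnings rather than load errors.

## Retrieval semantics

Criteria combine by conjunction only, mirroring faceted-search
interfaces; there is no boolean query language. Two expansions are on
by default, because the vocabulary stores hierarchy and inverse IRIs
precisely to enable them:

* **Hierarchy expansion**: a type criterion matches any record whose
  term lies in `descendants()` of the queried term (reflexive, so a
  term always matches itself).
* **Inverse matching**: a record matches if either its stored
  orientation or its reversed view satisfies the full conjunction.

`facet_counts()` tabulates one field over the filtered result. Zero
counts are omitted. For always-valued fields the counts partition the
result set, so they sum to its size; `importance` is optional, records
without a value are simply absent from that facet, and its counts may
sum to less.

The implementation flattens the dataset to a tibble once per query and
evaluates criteria as vectorised operations. The test suite checks it
against an independently written record-by-record evaluator on hundreds
of random criteria, plus a monotonicity property (adding a criterion
never enlarges the result).

## Serialisation choices

The canonical tabular format is one row per record with a fixed column
order, LF endings and UTF-8; `write_dataset()` output is byte-stable
and write→read→write is byte-identical, which the suite verifies on one
hundred seeded fixtures. Compound fields use simple doubling escapes:
classification paths are pipe-joined (literal `|` doubled), evidence
items are `kind:citation[:identifier]` joined by `;` (literal `:` and
`;` doubled). The evidence compound carries the optional identifier
precisely so that round-trips preserve every field. Coordinates are
written with up to 15 significant digits, enough for exact numeric
round-trips of decimal-degree values. Delimiters are inferred from the
extension (`.csv` comma, otherwise tab) and overridable. CSV quotes
fields containing delimiters or newlines; TSV has no quoting
convention, so embedded tabs/newlines are replaced by single spaces
with a warning.

The GloBI export is a 16-column tab-separated file, one row per record,
deterministic for a given dataset. Its column schema is this package's
own contract — the historical harvest feed's exact headers are not
public — chosen to carry every modelled field under GloBI-style names
(`sourceTaxonName`, `interactionTypeId`, ...) so a template mapping is
rename-only. One row per record, not per evidence item: the first
reference-kind citation is exported, other evidence summarised as a
comma-joined kind list, keeping the URL-per-interaction model intact.
`check_globi_file()` verifies the contract mechanically (header, field
counts, UTF-8, no raw tabs/newlines, required name columns non-empty)
and reports findings rather than raising.

## The synthetic-data generator

`generate_fixture()` emulates the two archetypes the model was shaped
by, with defaults chosen once from their qualitative descriptions:

| parameter | herbivory | parasitism | rationale |
|---|---|---|---|
| relation | "eats" | "ectoparasite of" | the archetypal relations |
| captive fraction | 0.20 | 0.05 | captive rearing is common for stick insects, rare for wild-collected lice |
| part fraction | 0.25 | 0.80 | lice records are typically body-region specific; plant parts noted occasionally |
| importance fraction | 0.15 | 0.05 | pest/crop notes appear on a minority of records |
| status mix (subject) | Native 0.7 / Introduced 0.3 | Native 0.9 / Introduced 0.1 | introduced organisms are the herbivory use case's focus |

The herbivory archetype additionally forces roughly a tenth of its
records into an introduced-insect × introduced-plant *Carausius
morosus* cluster located at San Diego — the motivating case for
establishment-status filtering — and records those UUIDs, along with
the UUIDs of native-on-native records, in its tally. The `mixed`
archetype draws each record from either archetype equiprobably.

Generation is deterministic end to end: sampling runs under the spec's
seed and record UUIDs are name-based (version 5, derived from seed,
archetype and index), so a spec reproduces byte-identical files across
machines. The generator also returns an exact tally of every status and
type it assigned, giving query and facet tests an oracle that was
bookkept during generation rather than recomputed.

What the fixtures do **not** emulate: real taxon-name messiness
(synonyms, misspellings, authorship strings), multi-evidence chains
with conflicting sources, coordinate uncertainty, or skewed abundance
distributions across taxa. Passing tests therefore demonstrate the
mechanics of validation, retrieval and serialisation, not robustness to
dirty real-world names — imports of real tables should expect to lean
on the lenient mode's violation report.

## Numerical and degenerate-input choices

* UUIDs are matched by syntax only (8-4-4-4-12 hex); version bits are
  not inspected, since imported identifiers may legitimately be v1 or
  v5.
* Probability vectors in `fixture_spec()` must sum to 1 within 1e-9.
* An empty dataset writes a header-only file, exports a one-line GloBI
  file, and yields empty facet maps; all are exercised in tests.
* Coordinate bounds are validated (latitude ±90, longitude ±180), and a
  half-present coordinate pair is a violation on the locality, not a
  crash.
* Facet ordering is deterministic: decreasing count, ties broken by
  label, so repeated runs print identically.

## Problem sizes used in the checks

The shipped suite validates the hierarchy oracle on two hundred random
forests of up to a thousand terms, the query engine against the naive
evaluator on a thousand-record fixture with fifty random criteria,
round-trips on a hundred fixtures, and validation completeness on a
thousand random mutations; `scripts/acceptance.R` re-runs the same
pipeline at comparable sizes. These sizes comfortably exceed the scale
of a typical curated association dataset while keeping a full run in
the low minutes on a single core.

## Known limitations

* No abiotic interactions (organism × building, vehicle, substrate);
  the relation vocabulary is inter-organism only.
* No event dates on records; recording time would be a natural future
  field.
* Single-parent hierarchies only; a true ontology DAG must be
  flattened before loading.
* The CLI's dataset file *is* the canonical table; dataset-level
  metadata beyond provenance keys does not survive the file format.
* Taxon matching is exact-string; no name resolution, synonymy or rank
  awareness.
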