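---
title: "Methods: minimum-information metadata engineering for fermentation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum-information metadata engineering for fermentation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermeta)
```

This vignette documents the model implemented by `fermeta`, the design
decisions that are not forced by any external standard, and the scope and
limitations of the bundled data generators. It states only what the package
computes; quantitative behaviour is established by the test suite, not
asserted here.

## The metadata model

`fermeta` operates on *minimum-information* schemas for industrial-biotech
fermentation: structured checklists that say which metadata terms must,
should, or may accompany an experiment or a device description.

A schema (`mim_schema`) is:

* an ordered set of **metadata levels** forming a parent chain. Two named
  hierarchies are built in: the experiment model
  (*investigation → study → observation unit → sample → assay*, an
  ISA-style extension) and the device model
  (*device → vessel → component*). Arbitrary hierarchies are supported via
  an explicit parent column.
* a set of **terms**, each attached to one level and carrying a value
  syntax, a strictness tier, an optional ontology mapping
  (predicate/object CURIEs), a multivalued flag, and — on levels that track
  measurement units — a preferred unit.

**Strictness tiers map to validation severities**: a missing *mandatory*
term is an `error`, a missing *recommended* term a `warning`, a missing
*optional* term is silent. This three-way mapping is the semantic core of
the model; every other check (identifier uniqueness, parent resolution,
token syntax, multiplicity, units) layers structural guarantees on top.

**Value syntaxes** form a closed 12-kind vocabulary: `string`, `text`,
`integer`, `decimal`, `boolean`, `date`, `datetime`, `url`, `email`,
`orcid`, `curie`, and `controlled` (an inline enumeration written
`controlled:{a|b|c}`). ORCID identifiers are checked with the ISO 7064
mod 11-2 checksum, implemented with the iterative doubling recurrence; the
test suite verifies it against an independent weighted-sum oracle. Dates
and datetimes are ISO 8601. CURIE prefixes are resolved against the
schema's prefix map when one is declared, otherwise checked syntactically.

## The spreadsheet dialect

Schemas travel as spreadsheets: a `metadata_levels` sheet plus one sheet
per level. Header and sheet-name matching is normalised (case, surrounding
whitespace, internal whitespace/underscores), so `Value Syntax` and
`value_syntax` are the same column. Decisions that the dialect itself does
not fix:

* The schema **name is not stored in the workbook**; `read_schema_workbook()`
  takes it as an argument, defaulting to the file stem. Names matching the
  built-in models (or level sets equal to theirs) get the fixed hierarchy;
  an explicit `parent level` column always wins. `write_schema_workbook()`
  always writes that column, so arbitrary hierarchies round-trip.
* Unknown columns on term sheets are preserved as opaque per-term
  annotations and written back verbatim.
* The prefix map round-trips through an optional `prefixes` sheet.

Filled templates use the same normalisation. Multiple values in one cell
are separated by a pipe (`|`, surrounding whitespace ignored); the pipe was
chosen because it cannot occur in any non-`string`/`text` syntax kind and
is rare in free text. The second template row is a `#strictness`
annotation row and is skipped on parsing.

**Unit policy.** On unit-tracking levels a numeric cell may carry a unit
suffix (`30.5 degree Celsius`). A unit differing from the term's preferred
unit yields a `UNIT_MISMATCH` *warning*, not an error: the value is still
syntactically valid and unit conversion is out of scope.

**Sibling parents.** A sample derived from another sample cites that
sample — a record at its *own* level — as its parent. The orphan check
therefore accepts a parent identifier resolving either in the declared
parent level or among sibling identifiers at the record's level. This is
what lets processed-sample chains validate and is what the provenance
builder keys on.

## Schema compilation

`compile_schema()` turns a schema into a LinkML-dialect document: one class
per level, one slot per term, plus a synthetic identifier slot per class
and a parent-reference slot per non-root class. Mandatory becomes
`required`; recommended becomes a `recommended` annotation rather than an
obligation. Controlled syntaxes become named enumerations; `url`, `email`,
`orcid` and `curie` carry regular-expression patterns. Key order is fixed
by construction, so emitting the same document twice produces
byte-identical YAML.

## RDF export

`export_rdf()` refuses datasets with validation errors, then emits one
`rdf:type` triple per record, one containment triple per resolved parent
link, and one property triple per populated **declared-term** token.
Unknown-term cells are *not* exported: they already produced a validation
warning, and exporting ungoverned columns would make the graph's shape
depend on typos. This gives a closed-form triple count (the conservation
law the tests check against an independent walker).

Numeric tokens carrying a unit are exported as plain literals
(`"30.5 degree Celsius"`) rather than split into value/unit nodes —
faithful to the cell, at the cost of not being numerically queryable.
Other typed kinds get XSD datatypes. CURIE objects become IRIs via the
prefix map. The containment predicate defaults to `<base>hasPart` and is
configurable. Triples are sorted, and both Turtle and N-Triples writers
use binary connections, so output is byte-deterministic.

## Provenance backbone

`build_cpm_backbone()` derives a chain of *main activities* with fixed
connector role sets:

| activity | backward (inputs) | forward (outputs) |
|---|---|---|
| observation unit | sample, vessel, protocol, feed materials, chemical compounds | data for analysis, logfiles |
| sample processing | sample | processed sample(s) |
| sample collection | source | sample |

One observation-unit activity is created per observation-unit record and
one sample activity per sample record (processing when the sample's parent
is itself a sample, collection otherwise), so the activity count is the
sum of those two record counts. Term-to-role matching is substring-based
on term names and overridable via `role_map`. Activities sharing an
entity are chained producer → consumer, and the result must be acyclic
(Kahn's algorithm). `serialize_backbone()` emits exactly
1 + backward + forward PROV triples per activity (`prov:used` /
`prov:generated`).

## Fixture generators

The generators are the package's study material, not demo toys; their
defaults are the study conditions and were fixed before the test suite was
written, not tuned afterwards.

* `make_fixture_schema("mife_subset")` — a 20-term, 5-level experiment
  subset (4 mandatory, 5 recommended, 11 optional; 4 ontology-mapped
  terms; one controlled, one ORCID, two multivalued, two unit-bearing
  terms). `"mifd_subset"` is the 7-term, 3-level device analogue.
  `"random"` draws a 2–5 level chain with 2–6 terms per level and random
  kinds/strictness/flags from the seed.
* `make_fixture_dataset()` generates parent-consistent records
  (default 2, 3, 3, 4, 5 per level on the experiment subset), populating
  mandatory and recommended terms always and optional terms with
  probability 0.7, then **injects a requested number of violations** from
  a five-code cycle (missing mandatory, bad syntax, orphan, duplicate
  identifier, multivalue on single). Each violation reserves a whole
  record so injections cannot mask one another, and the manifest records
  exactly what was planted — the oracle the validator is scored against.

All randomness flows through a single seed with save/restore of the RNG
state, so fixtures are byte-reproducible.

**Scope and limitations.** The subset schemas are deliberately small
stand-ins: the full published experiment and device checklists (89 and 26
ontology-mapped terms respectively) are external supplementary artefacts
and are not bundled. The random generator covers linear hierarchies only,
not forests; violation injection covers the five codes above, not the
cross-reference or unit codes; and the unit model checks labels, it does
not convert. `orcid_check_digit()` assumes 15 base digits and is not a
general ISO 7064 implementation. Problem sizes in the acceptance script
(replicate counts, ORCID sample size) are the package's own choices, made
for runtime, not prescribed by any standard.
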