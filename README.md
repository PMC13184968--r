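# fermeta

Minimum-information metadata engineering for industrial-biotech
fermentation studies.

## The problem

Fermentation experiments produce data that is only reusable if the
surrounding metadata — which strain, which vessel, which feed, which
sampling and assay steps — is captured completely and consistently.
Minimum-information checklists solve this on paper: hierarchical models
for experiments (*investigation → study → observation unit → sample →
assay*) and for the devices they run on (*device → vessel → component*),
with every term assigned a strictness tier (**mandatory / recommended /
optional**), a value syntax, and optional ontology mappings. In practice
these checklists live in spreadsheets, and nothing enforces them.

`fermeta` makes such checklists executable. It:

* reads and writes the spreadsheet schema dialect (a `metadata_levels`
  sheet plus one term sheet per level) with full round-trip fidelity;
* **compiles** a schema into a LinkML-dialect YAML document (classes,
  slots, enumerations, patterns);
* generates fill-in templates and **validates** filled templates, mapping
  strictness to severity (mandatory → error, recommended → warning,
  optional → silent) alongside structural checks: identifier uniqueness,
  parent resolution, value syntax (ISO 8601 dates, ORCID checksums,
  CURIEs, controlled vocabularies), multiplicity, and preferred units;
* **exports** valid datasets as RDF (Turtle / N-Triples) with
  deterministic, byte-stable output;
* derives a **provenance backbone** of main activities (observation unit,
  sample collection, sample processing) with fixed backward/forward
  connector roles, serialised as PROV;
* ships seeded **fixture generators** whose violation manifests act as a
  ground-truth oracle for the validator;
* exposes everything through a CLI (`inst/cli/fermeta`).

## Worked example

```r
library(fermeta)

fx <- make_fixture_schema("mife_subset")   # 20-term experiment subset
schema <- fx$schema
schema
#> <mim_schema> MIFE_subset: 5 level(s), 20 term(s), 4 mapped to KOS
#>   levels: investigation > study > observation unit > sample > assay

# generate a dataset with three seeded violations and validate it
ds <- make_fixture_dataset(schema, violations = 3, seed = 42)
report <- validate_dataset(schema, ds$dataset)
report
#> <validation_report> FAIL: 3 error(s), 0 warning(s), 3 info
#>   [error] BAD_SYNTAX investigation/investigation-1 (principal investigator orcid): token '?not!a/value?' does not match syntax 'orcid'
#>   [error] ORPHAN_RECORD study/study-3: parent identifier 'no-such-parent' does not name a investigation record
#>   [info] CROSS_REF_SKIPPED observation unit/observation-unit-1 (vessel identifier): vessel reference 'aerobic-35' not checked (no device dataset loaded)
#>   [info] CROSS_REF_SKIPPED observation unit/observation-unit-2 (vessel identifier): vessel reference 'fedbatch-21' not checked (no device dataset loaded)
#>   [info] CROSS_REF_SKIPPED observation unit/observation-unit-3 (vessel identifier): vessel reference 'citrate-43' not checked (no device dataset loaded)
#>   [error] MISSING_MANDATORY assay/assay-4 (assay type): mandatory term 'assay type' is empty
```

The three errors are exactly the three violations the generator's
manifest says it planted (`ds$manifest$violations`). A clean dataset
compiles, exports and chains:

```r
clean <- make_fixture_dataset(schema, seed = 42)
g <- export_rdf(schema, clean$dataset)
nrow(g$triples)
#> [1] 85

build_cpm_backbone(schema, clean$dataset)
#> <cpm_backbone> 7 activity(ies) [observation_unit: 3, sample_collection: 4], 21 connector(s), 4 chain edge(s)

compile_schema(schema)
#> <schema_document> MIFE_subset: 5 class(es), 29 slot(s) (20 term, 4 required), 1 enum(s)
```

`write_schema_workbook()` / `read_schema_workbook()` round-trip schemas
through `.xlsx`; `generate_template()` / `parse_filled_template()` do the
same for data entry; `emit_yaml()`, `write_rdf()`, `report_to_json()` and
`serialize_backbone()` write the derived artefacts. The same operations
are available from the command line:

```sh
inst/cli/fermeta fixtures --profile mife_subset --seed 1 -o out/
inst/cli/fermeta validate --schema out/schema.xlsx --data out/dataset.xlsx --report report.json
```

(exit code 0 = valid, 1 = validation errors, 2 = usage/IO failure).

## License

MIT — see `LICENSE`.
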