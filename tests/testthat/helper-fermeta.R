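# Shared helpers: cached fixture schemas, independent counting oracles.

mife_fx <- make_fixture_schema("mife_subset")
mifd_fx <- make_fixture_schema("mifd_subset")

tmp_xlsx <- function() tempfile(fileext = ".xlsx")

# Independent ORCID oracle: ISO 7064 mod 11-2 in its weighted-sum form —
# an identifier is valid iff sum(d_i * 2^(16-i)) mod 11 == 1, with the
# check character X standing for 10. (The implementation under test uses
# the iterative doubling recurrence instead.)
orcid_oracle <- function(token) {
  chars <- strsplit(gsub("-", "", token), "")[[1]]
  if (length(chars) != 16) return(FALSE)
  d <- suppressWarnings(as.integer(chars))
  if (chars[16] == "X") d[16] <- 10L
  if (anyNA(d)) return(FALSE)
  weights <- 2^(16 - seq_len(16))
  sum(d * weights) %% 11 == 1
}

# Independent triple-count oracle: walk the dataset and count
# 1 type + [resolved parent] + one per populated declared-term token.
triple_count_oracle <- function(schema, dataset) {
  recs <- dataset$records
  total <- 0L
  for (i in seq_len(nrow(recs))) {
    lv <- schema$levels[match(tolower(recs$level[i]), tolower(schema$levels$name)), ]
    if (is.na(lv$name)) next
    total <- total + 1L
    if (!is.na(lv$parent_level) && !is.na(recs$parent_identifier[i])) total <- total + 1L
    tm <- schema$terms[tolower(schema$terms$level) == tolower(recs$level[i]), ]
    v <- recs$values[[i]]
    total <- total + sum(lengths(v[names(v) %in% tm$name]))
  }
  total
}

error_codes <- function(report) {
  sort(report$findings$code[report$findings$severity == "error"])
}

manifest_codes <- function(manifest) {
  sort(vapply(manifest$violations, `[[`, character(1), "code"))
}

# small generic 2-level schema built in code (not via fixtures)
tiny_schema <- function() {
  levels <- tibble::tibble(
    name = c("plate", "well"),
    description = c("culture plate", "single well"),
    mapped_object = NA_character_, extends = NA_character_,
    parent_level = c(NA, "plate"),
    unit_column_present = c(FALSE, TRUE))
  terms <- tibble::tibble(
    name = c("plate id code", "incubation temp", "carbon source", "reviewed"),
    level = c("plate", "well", "well", "well"),
    syntax = c("string", "decimal", "controlled", "boolean"),
    allowed_values = list(character(0), character(0),
                          c("glucose", "galactose"), character(0)),
    definition = NA_character_, example = NA_character_,
    strictness = c("mandatory", "recommended", "optional", "optional"),
    predicate = NA_character_, mapped_object = c(NA, "om:Temperature", NA, NA),
    multivalued = c(FALSE, FALSE, TRUE, FALSE),
    preferred_unit = c(NA, "degree Celsius", NA, NA),
    extra = list(NULL, NULL, NULL, NULL))
  mim_schema("plate_assay", levels, terms,
             c(om = "http://www.ontology-of-units-of-measure.org/resource/om-2/"))
}

record_tbl <- function(level, identifier, parent = NA_character_, values = list()) {
  tibble::tibble(level = level, identifier = identifier,
                 parent_identifier = parent, values = list(values))
}
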