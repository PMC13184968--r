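test_that("templates have one sheet per level with the documented header layout", {
  s <- mife_fx$schema
  p <- tmp_xlsx()
  generate_template(s, p)
  sheets <- read_xlsx_sheets(p)
  expect_equal(names(sheets), s$levels$name)
  for (k in seq_len(nrow(s$levels))) {
    lname <- s$levels$name[k]
    n_terms <- sum(s$terms$level == lname)
    is_root <- is.na(s$levels$parent_level[k])
    expect_equal(ncol(sheets[[lname]]),
                 (if (is_root) 1 else 2) + n_terms, info = lname)
    expect_equal(names(sheets[[lname]])[1], "identifier")
    if (!is_root) expect_equal(names(sheets[[lname]])[2], "parent identifier")
  }
  # annotation row is skipped: an untouched template parses as empty
  ds <- parse_filled_template(s, p)
  expect_equal(nrow(ds$records), 0L)
})

test_that("multivalued cells split on pipe with whitespace trimmed", {
  s <- mife_fx$schema
  p <- tmp_xlsx()
  rec <- record_tbl("observation unit", "ou-1", "study-1",
                    list(`strain` = "x", `feed medium` = c("glucose", "galactose")))
  write_filled_template(s, metadata_dataset(s$name, rec), p)
  ds <- parse_filled_template(s, p)
  expect_equal(ds$records$values[[1]][["feed medium"]], c("glucose", "galactose"))
})

test_that("parsed record counts match the fixture manifest", {
  s <- mife_fx$schema
  fx <- make_fixture_dataset(s, violations = 0, seed = 8, path = tmp_xlsx())
  ds <- parse_filled_template(s, fx$path)
  expect_equal(nrow(ds$records), fx$manifest$n_records)
  expect_identical(ds, fx$dataset)
})

test_that("a violation-free fixture dataset validates cleanly", {
  for (seed in c(1, 2, 3)) {
    fx <- make_fixture_dataset(mife_fx$schema, violations = 0, seed = seed)
    report <- validate_dataset(mife_fx$schema, fx$dataset)
    expect_true(report$pass)
    expect_equal(report$counts[["error"]], 0L)
  }
})

test_that("seeded violations are recovered exactly, through the workbook", {
  s <- mife_fx$schema
  fx <- make_fixture_dataset(s, violations = 7, seed = 17, path = tmp_xlsx())
  ds <- parse_filled_template(s, fx$path)
  report <- validate_dataset(s, ds)
  expect_equal(report$counts[["error"]], 7L)
  expect_identical(error_codes(report), manifest_codes(fx$manifest))
  expect_false(report$pass)
})

test_that("a record lacking its mandatory strain term yields one finding naming it", {
  s <- mife_fx$schema
  rec <- record_tbl("observation unit", "ou-1", "study-1",
                    list(`vessel identifier` = "v1"))
  parents <- rbind(record_tbl("investigation", "inv-1", values = list(`investigation title` = "t")),
                   record_tbl("study", "study-1", "inv-1", list(`study title` = "t")))
  ds <- metadata_dataset(s$name, rbind(parents, rec))
  report <- validate_dataset(s, ds)
  hits <- report$findings[report$findings$code == "MISSING_MANDATORY" &
                            report$findings$level == "observation unit", ]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$term, "strain")
})

test_that("structural findings: orphans, duplicates, multivalue, unknown terms", {
  s <- mife_fx$schema
  recs <- rbind(
    record_tbl("investigation", "inv-1", values = list(`investigation title` = "t")),
    record_tbl("investigation", "inv-1", values = list(`investigation title` = "t")),
    record_tbl("study", "st-1", "ghost", list(`study title` = "t")),
    record_tbl("study", "st-2", "inv-1",
               list(`study title` = c("two", "titles"), `made up column` = "x")))
  report <- validate_dataset(s, metadata_dataset(s$name, recs))
  codes <- table(report$findings$code)
  expect_equal(unname(codes[["DUP_IDENTIFIER"]]), 1L)
  expect_equal(unname(codes[["ORPHAN_RECORD"]]), 1L)
  expect_equal(unname(codes[["MULTIVALUE_ON_SINGLE"]]), 1L)
  expect_equal(unname(codes[["UNKNOWN_TERM"]]), 1L)
  expect_equal(report$findings$severity[report$findings$code == "UNKNOWN_TERM"], "warning")
})

test_that("unit handling: bare numbers pass, deviating units warn but do not fail", {
  s <- tiny_schema()
  recs <- rbind(
    record_tbl("plate", "p1", values = list(`plate id code` = "p1")),
    record_tbl("well", "w1", "p1", list(`incubation temp` = "30.5")),
    record_tbl("well", "w2", "p1", list(`incubation temp` = "30.5 degree Celsius")),
    record_tbl("well", "w3", "p1", list(`incubation temp` = "303 kelvin")))
  report <- validate_dataset(s, metadata_dataset(s$name, recs))
  expect_equal(report$counts[["error"]], 0L)
  um <- report$findings[report$findings$code == "UNIT_MISMATCH", ]
  expect_equal(um$identifier, "w3")
  expect_true(report$pass)
})

test_that("missing-term severity is a function of strictness alone", {
  for (seed in c(5, 21)) {
    s <- make_fixture_schema("random", seed)$schema
    root <- s$levels$name[is.na(s$levels$parent_level)][1]
    tm <- s$terms[s$terms$level == root, ]
    ds <- metadata_dataset(s$name, record_tbl(root, "r1", values = list()))
    report <- validate_dataset(s, ds)
    expect_equal(sum(report$findings$code == "MISSING_MANDATORY"),
                 sum(tm$strictness == "mandatory"))
    expect_equal(sum(report$findings$code == "MISSING_RECOMMENDED"),
                 sum(tm$strictness == "recommended"))
    expect_equal(sum(report$findings$code %in% c("MISSING_MANDATORY", "MISSING_RECOMMENDED")),
                 sum(tm$strictness != "optional"))
  }
})

test_that("error counts are monotone under added violations", {
  s <- mife_fx$schema
  for (k in c(0, 2, 4)) {
    fx <- make_fixture_dataset(s, violations = k, seed = 31 + k)
    base <- validate_dataset(s, fx$dataset)$counts[["error"]]
    expect_equal(base, k)
    # knock out one populated mandatory cell by hand
    recs <- fx$dataset$records
    hit <- NULL
    for (r in seq_len(nrow(recs))) {
      tm <- s$terms[s$terms$level == recs$level[r] & s$terms$strictness == "mandatory", ]
      pop <- intersect(tm$name, names(recs$values[[r]]))
      if (length(pop) > 0) { hit <- list(r = r, term = pop[1]); break }
    }
    recs$values[[hit$r]][[hit$term]] <- NULL
    worse <- validate_dataset(s, metadata_dataset(s$name, recs))$counts[["error"]]
    expect_equal(worse, base + 1L)
  }
})

test_that("every non-orphan record's parent chain reaches a root level", {
  s <- mife_fx$schema
  fx <- make_fixture_dataset(s, violations = 0, seed = 13)
  recs <- fx$dataset$records
  roots <- s$levels$name[is.na(s$levels$parent_level)]
  for (r in seq_len(nrow(recs))) {
    level <- recs$level[r]; id <- recs$identifier[r]
    steps <- 0
    while (!(level %in% roots)) {
      pid <- recs$parent_identifier[recs$level == level & recs$identifier == id][1]
      plevel <- s$levels$parent_level[s$levels$name == level]
      expect_true(pid %in% recs$identifier[recs$level == plevel])
      id <- pid; level <- plevel; steps <- steps + 1
      expect_lt(steps, 10)
    }
  }
})

test_that("validation is idempotent and reports are deterministically sorted", {
  fx <- make_fixture_dataset(mife_fx$schema, violations = 5, seed = 23)
  r1 <- validate_dataset(mife_fx$schema, fx$dataset)
  r2 <- validate_dataset(mife_fx$schema, fx$dataset)
  expect_identical(r1$findings, r2$findings)
  expect_identical(r1$counts, r2$counts)
})

test_that("vessel references are info-skipped alone, checked against a co-loaded device dataset", {
  s <- mife_fx$schema
  fx <- make_fixture_dataset(s, violations = 0, seed = 2)
  alone <- validate_dataset(s, fx$dataset)
  expect_gt(sum(alone$findings$code == "CROSS_REF_SKIPPED"), 0)
  expect_true(alone$pass)
  md <- mifd_fx$schema
  mdd <- make_fixture_dataset(md, violations = 0, seed = 2)
  co <- validate_dataset(s, fx$dataset, mifd_dataset = mdd$dataset)
  expect_equal(sum(co$findings$code == "CROSS_REF_SKIPPED"), 0)
  expect_gt(sum(co$findings$code == "CROSS_REF_UNRESOLVED"), 0)  # fixture ids differ
})

test_that("schema/dataset name mismatch is fatal", {
  fx <- make_fixture_dataset(mife_fx$schema, seed = 1)
  expect_error(validate_dataset(mifd_fx$schema, fx$dataset),
               class = "fermeta_format_error")
})

test_that("validation reports serialise to versioned JSON", {
  fx <- make_fixture_dataset(mife_fx$schema, violations = 2, seed = 6)
  report <- validate_dataset(mife_fx$schema, fx$dataset)
  p <- tempfile(fileext = ".json")
  report_to_json(report, p)
  parsed <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(parsed$report_version, 1L)
  expect_false(parsed$pass)
  expect_equal(parsed$counts$error, 2L)
  expect_equal(nrow(parsed$findings), nrow(report$findings))
})
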