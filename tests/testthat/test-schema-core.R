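test_that("experiment fixture schema has the five-level ISA-extended chain", {
  s <- mife_fx$schema
  expect_equal(s$levels$name,
               c("investigation", "study", "observation unit", "sample", "assay"))
  expect_equal(s$levels$parent_level,
               c(NA, "investigation", "study", "observation unit", "sample"))
  expect_equal(mifd_fx$schema$levels$name, c("device", "vessel", "component"))
})

test_that("schema workbook round-trips field-for-field", {
  for (s in list(mife_fx$schema, mifd_fx$schema, tiny_schema())) {
    p <- tmp_xlsx()
    write_schema_workbook(s, p)
    expect_identical(read_schema_workbook(p, name = s$name), s)
  }
})

test_that("empty metadata_levels sheet parses to an empty schema and round-trips", {
  p <- tmp_xlsx()
  write_xlsx_sheets(list(metadata_levels = data.frame(
    `metadata level` = character(0), description = character(0),
    check.names = FALSE)), p)
  s <- read_schema_workbook(p, name = "blank")
  expect_equal(nrow(s$levels), 0L)
  expect_equal(nrow(s$terms), 0L)
  expect_equal(count_mapped_terms(s), 0L)
  p2 <- tmp_xlsx()
  write_schema_workbook(s, p2)
  expect_identical(read_schema_workbook(p2, name = "blank"), s)
})

test_that("reader counts match the fixture manifest", {
  for (fx in list(mife_fx, mifd_fx, make_fixture_schema("random", 42))) {
    p <- tmp_xlsx()
    write_schema_workbook(fx$schema, p)
    s <- read_schema_workbook(p, name = fx$schema$name)
    expect_equal(nrow(s$levels), fx$manifest$n_levels)
    expect_equal(nrow(s$terms), fx$manifest$n_terms)
    expect_equal(sum(s$terms$strictness == "mandatory"),
                 fx$manifest$n_terms_by_strictness$mandatory)
    expect_equal(count_mapped_terms(s), fx$manifest$n_mapped_terms)
  }
})

test_that("reader is invariant to column and row order within sheets", {
  s <- tiny_schema()
  p <- tmp_xlsx()
  write_schema_workbook(s, p)
  sheets <- read_xlsx_sheets(p)
  shuffled <- lapply(sheets, function(df) {
    df <- df[, rev(seq_along(df)), drop = FALSE]
    df
  })
  # also shuffle level rows (term order within a level must be preserved)
  shuffled$metadata_levels <- shuffled$metadata_levels[rev(seq_len(nrow(shuffled$metadata_levels))), , drop = FALSE]
  p2 <- tmp_xlsx()
  write_xlsx_sheets(shuffled, p2)
  s2 <- read_schema_workbook(p2, name = s$name)
  expect_equal(sort(s2$levels$name), sort(s$levels$name))
  expect_identical(s2$terms, s$terms[order(match(s$terms$level, s2$levels$name)), ])
})

test_that("header matching tolerates case, whitespace and underscores", {
  s <- tiny_schema()
  p <- tmp_xlsx()
  write_schema_workbook(s, p)
  sheets <- read_xlsx_sheets(p)
  names(sheets$metadata_levels)[names(sheets$metadata_levels) == "metadata level"] <- "Metadata_Level"
  names(sheets$well)[names(sheets$well) == "value syntax"] <- "  VALUE   SYNTAX "
  p2 <- tmp_xlsx()
  write_xlsx_sheets(sheets, p2)
  expect_identical(read_schema_workbook(p2, name = s$name), s)
})

test_that("unknown extra columns are preserved through a round trip", {
  s <- tiny_schema()
  p <- tmp_xlsx()
  write_schema_workbook(s, p)
  sheets <- read_xlsx_sheets(p)
  sheets$well$curator <- c("alice", NA, "bob", NA)[seq_len(nrow(sheets$well))]
  p2 <- tmp_xlsx()
  write_xlsx_sheets(sheets, p2)
  s2 <- read_schema_workbook(p2, name = s$name)
  well_terms <- s2$terms[s2$terms$level == "well", ]
  expect_true(any(vapply(s2$terms$extra, function(e) "curator" %in% names(e), logical(1))))
  p3 <- tmp_xlsx()
  write_schema_workbook(s2, p3)
  expect_identical(read_schema_workbook(p3, name = s$name), s2)
})

test_that("schema format errors are fatal and specific", {
  # no metadata_levels sheet
  p <- tmp_xlsx()
  write_xlsx_sheets(list(stuff = data.frame(x = "1")), p)
  expect_error(read_schema_workbook(p), class = "fermeta_format_error")
  # level declared but sheet missing
  p2 <- tmp_xlsx()
  write_xlsx_sheets(list(metadata_levels = data.frame(
    `metadata level` = "ghost", description = "no sheet", check.names = FALSE)), p2)
  expect_error(read_schema_workbook(p2, name = "g"), class = "fermeta_format_error")
})

test_that("unknown strictness tokens are schema errors naming the row", {
  p <- tmp_xlsx()
  write_xlsx_sheets(list(
    metadata_levels = data.frame(`metadata level` = "lvl", description = "d",
                                 check.names = FALSE),
    lvl = data.frame(term = c("ok", "odd"), `value syntax` = c("string", "string"),
                     strictness = c("mandatory", "sometimes"),
                     check.names = FALSE)), p)
  expect_error(read_schema_workbook(p, name = "x"),
               regexp = "sometimes", class = "fermeta_schema_error")
})

test_that("duplicate (term, level) pairs are schema errors", {
  p <- tmp_xlsx()
  write_xlsx_sheets(list(
    metadata_levels = data.frame(`metadata level` = "lvl", description = "d",
                                 check.names = FALSE),
    lvl = data.frame(term = c("dup", "Dup"), `value syntax` = c("string", "string"),
                     strictness = c("optional", "optional"),
                     check.names = FALSE)), p)
  expect_error(read_schema_workbook(p, name = "x"), class = "fermeta_schema_error")
})

test_that("cyclic parent edges between levels are rejected", {
  p <- tmp_xlsx()
  write_xlsx_sheets(list(
    metadata_levels = data.frame(`metadata level` = c("a", "b"),
                                 description = c("d", "d"),
                                 `parent level` = c("b", "a"),
                                 check.names = FALSE),
    a = data.frame(term = "t1", `value syntax` = "string",
                   strictness = "optional", check.names = FALSE),
    b = data.frame(term = "t2", `value syntax` = "string",
                   strictness = "optional", check.names = FALSE)), p)
  expect_error(read_schema_workbook(p, name = "loop"),
               regexp = "cycle", class = "fermeta_schema_error")
})

test_that("value syntax tokens parse and serialise symmetrically", {
  v <- parse_value_syntax("controlled:{bioreactor|microwell|flask}")
  expect_equal(v$kind, "controlled")
  expect_equal(v$allowed_values, c("bioreactor", "microwell", "flask"))
  expect_equal(format_value_syntax(v), "controlled:{bioreactor|microwell|flask}")
  expect_equal(format_value_syntax(parse_value_syntax("orcid")), "orcid")
  expect_error(parse_value_syntax("hologram"), class = "fermeta_schema_error")
  expect_error(value_syntax("controlled"), class = "fermeta_schema_error")
})

test_that("preferred units are only allowed on unit-tracking levels", {
  s <- tiny_schema()
  bad_terms <- s$terms
  bad_terms$preferred_unit[bad_terms$name == "plate id code"] <- "gram"
  expect_error(mim_schema(s$name, s$levels, bad_terms, s$prefix_map),
               class = "fermeta_schema_error")
})
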