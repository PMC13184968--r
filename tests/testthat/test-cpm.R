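cpm_role_sets <- list(
  observation_unit = list(
    backward = c("sample", "vessel", "protocol", "feed_materials", "chemical_compounds"),
    forward = c("data_for_analysis", "logfiles")),
  sample_processing = list(backward = "sample", forward = "processed_sample"),
  sample_collection = list(backward = "source", forward = "sample"))

test_that("an empty dataset yields an empty backbone", {
  bb <- build_cpm_backbone(mife_fx$schema, metadata_dataset("MIFE_subset"))
  expect_equal(nrow(bb$activities), 0L)
  expect_equal(nrow(bb$connectors), 0L)
})

test_that("a lone run with vessel and protocol terms gets exactly those input roles", {
  s <- mife_fx$schema
  recs <- rbind(
    record_tbl("investigation", "inv-1", values = list(`investigation title` = "t")),
    record_tbl("study", "st-1", "inv-1", list(`study title` = "t")),
    record_tbl("observation unit", "ou-1", "st-1",
               list(strain = "W303", `vessel identifier` = "v-7",
                    `cultivation protocol` = "https://example.org/sop/3")))
  bb <- build_cpm_backbone(s, metadata_dataset(s$name, recs))
  act <- bb$activities[bb$activities$kind == "observation_unit", ]
  expect_equal(nrow(act), 1L)
  back <- bb$connectors[bb$connectors$activity == act$id &
                          bb$connectors$direction == "backward", ]
  expect_setequal(back$role, c("vessel", "protocol"))
  expect_true(all(back$role %in% cpm_role_sets$observation_unit$backward))
})

test_that("activity counts equal observation-unit plus sample records", {
  for (seed in c(1, 7, 19)) {
    fx <- make_fixture_dataset(mife_fx$schema, violations = 0, seed = seed)
    recs <- fx$dataset$records
    bb <- build_cpm_backbone(mife_fx$schema, fx$dataset)
    n_ou <- sum(recs$level == "observation unit")
    n_s <- sum(recs$level == "sample")
    expect_equal(nrow(bb$activities), n_ou + n_s)
    expect_equal(sum(bb$activities$kind == "observation_unit"), n_ou)
    expect_equal(sum(bb$activities$kind == "sample_collection"), n_s)
    # chain edges: one per sample consumed by its run
    expect_equal(nrow(bb$edges), n_s)
  }
})

test_that("no connector role ever falls outside the fixed role sets", {
  for (seed in c(2, 11, 29)) {
    fx <- make_fixture_dataset(mife_fx$schema, violations = 0, seed = seed)
    bb <- build_cpm_backbone(mife_fx$schema, fx$dataset)
    for (i in seq_len(nrow(bb$connectors))) {
      kind <- bb$activities$kind[bb$activities$id == bb$connectors$activity[i]]
      expect_true(bb$connectors$role[i] %in%
                    cpm_role_sets[[kind]][[bb$connectors$direction[i]]])
    }
  }
})

test_that("a sample parented to another sample becomes a processing activity", {
  s <- mife_fx$schema
  recs <- rbind(
    record_tbl("investigation", "inv-1", values = list(`investigation title` = "t")),
    record_tbl("study", "st-1", "inv-1", list(`study title` = "t")),
    record_tbl("observation unit", "ou-1", "st-1", list(strain = "W303")),
    record_tbl("sample", "s-raw", "ou-1", list(`source material` = "broth")),
    record_tbl("sample", "s-proc", "s-raw", list()))
  bb <- build_cpm_backbone(s, metadata_dataset(s$name, recs))
  expect_equal(sum(bb$activities$kind == "sample_processing"), 1L)
  proc <- bb$activities$id[bb$activities$kind == "sample_processing"]
  pc <- bb$connectors[bb$connectors$activity == proc, ]
  expect_setequal(pc$role[pc$direction == "backward"], "sample")
  expect_setequal(pc$role[pc$direction == "forward"], "processed_sample")
  # collection -> processing chain through the shared raw sample
  expect_true(any(bb$edges$to == proc & bb$edges$entity == "s-raw"))
})

test_that("the entity-sharing chain over activities is acyclic", {
  for (seed in c(3, 13)) {
    fx <- make_fixture_dataset(mife_fx$schema, violations = 0, seed = seed)
    expect_no_error(build_cpm_backbone(mife_fx$schema, fx$dataset))
  }
})

test_that("unvalidated datasets are refused", {
  fx <- make_fixture_dataset(mife_fx$schema, violations = 2, seed = 9)
  expect_error(build_cpm_backbone(mife_fx$schema, fx$dataset),
               class = "fermeta_cpm_error")
})

test_that("PROV serialisation emits 1 + backward + forward triples per activity", {
  s <- mife_fx$schema
  recs <- rbind(
    record_tbl("investigation", "inv-1", values = list(`investigation title` = "t")),
    record_tbl("study", "st-1", "inv-1", list(`study title` = "t")),
    record_tbl("observation unit", "ou-1", "st-1",
               list(strain = "W303", `vessel identifier` = "v-7",
                    `cultivation protocol` = "https://example.org/sop/3")))
  bb <- build_cpm_backbone(s, metadata_dataset(s$name, recs))
  ts <- serialize_backbone(bb)
  expect_equal(nrow(ts$triples), 1L + 2L + 0L)  # type + 2 usage, no outputs
  fx <- make_fixture_dataset(s, violations = 0, seed = 21)
  bb2 <- build_cpm_backbone(s, fx$dataset)
  ts2 <- serialize_backbone(bb2)
  expect_equal(nrow(ts2$triples), nrow(bb2$activities) + nrow(bb2$connectors))
  p1 <- tempfile(); p2 <- tempfile()
  serialize_backbone(bb2, p1); serialize_backbone(bb2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(any(grepl("prov:used", readLines(p1))))
})

test_that("an empty backbone serialises to zero triples", {
  bb <- build_cpm_backbone(mife_fx$schema, metadata_dataset("MIFE_subset"))
  expect_equal(nrow(serialize_backbone(bb)$triples), 0L)
})
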