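# Deterministic fixture generators.
#
# Bundled subset schemas echo the experiment (MIFE) and device (MIFD)
# models — the five-level ISA-extended chain and the three-level device
# chain with their exemplar terms (a mandatory strain, an ORCID, a
# unit-bearing numeric sample term, a controlled vessel type) — but are
# explicitly NOT the full published term catalogues, which live in external
# supplementary workbooks. A third profile draws random schemas for
# property tests. Everything is reproducible: the same seed yields
# byte-identical workbooks and manifests.

FIXTURE_PREFIXES <- c(
  obo = "http://purl.obolibrary.org/obo/",
  om = "http://www.ontology-of-units-of-measure.org/resource/om-2/",
  jerm = "http://jermontology.org/ontology/JERMOntology#",
  schema = "https://schema.org/"
)

WORD_POOL <- c("glucose", "galactose", "lactose", "yeast", "pichia", "coli",
               "batch", "fedbatch", "aerobic", "anaerobic", "biomass",
               "penicillin", "ethanol", "citrate", "sensor", "probe")

fixture_term <- function(name, level, syntax, strictness,
                         allowed = character(0), definition = NA_character_,
                         example = NA_character_, predicate = NA_character_,
                         object = NA_character_, multivalued = FALSE,
                         unit = NA_character_) {
  tibble::tibble(name = name, level = level, syntax = syntax,
                 allowed_values = list(allowed), definition = definition,
                 example = example, strictness = strictness,
                 predicate = predicate, mapped_object = object,
                 multivalued = multivalued, preferred_unit = unit,
                 extra = list(NULL))
}

mife_subset_schema <- function() {
  levels <- tibble::tibble(
    name = c("investigation", "study", "observation unit", "sample", "assay"),
    description = c("Top-level research project context.",
                    "A set of related fermentation experiments.",
                    "A single fermentation run on a piece of equipment.",
                    "Culture volume taken from a run at any process step.",
                    "An analytical assay applied to a sample."),
    mapped_object = c("jerm:Investigation", "jerm:Study", NA, NA, "jerm:Assay"),
    extends = c("jerm:Investigation", "jerm:Study", NA, NA, "jerm:Assay"),
    parent_level = c(NA, "investigation", "study", "observation unit", "sample"),
    unit_column_present = c(FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  terms <- rbind(
    fixture_term("investigation title", "investigation", "string", "mandatory",
                 definition = "Short title of the investigation.",
                 example = "Penicillin process optimisation",
                 predicate = "schema:name"),
    fixture_term("principal investigator orcid", "investigation", "orcid", "recommended",
                 definition = "ORCID of the lead researcher.",
                 example = "0000-0002-1825-0097", predicate = "schema:identifier"),
    fixture_term("investigation description", "investigation", "text", "optional",
                 definition = "Free-text summary."),
    fixture_term("study title", "study", "string", "mandatory",
                 definition = "Short title of the study.", predicate = "schema:name"),
    fixture_term("start date", "study", "date", "recommended",
                 definition = "ISO 8601 start date.", example = "2025-05-01"),
    fixture_term("related publication", "study", "url", "optional",
                 definition = "Link to an associated publication."),
    fixture_term("strain", "observation unit", "string", "mandatory",
                 definition = "Microbial strain used as cell factory.",
                 example = "Penicillium chrysogenum Wis54-1255",
                 predicate = "jerm:hasPart", object = "obo:OBI_0100026"),
    fixture_term("vessel identifier", "observation unit", "string", "recommended",
                 definition = "Identifier of the fermentation vessel used."),
    fixture_term("cultivation protocol", "observation unit", "url", "optional",
                 definition = "Link to the cultivation protocol."),
    fixture_term("feed medium", "observation unit", "string", "optional",
                 definition = "Feed materials supplied during the run.",
                 multivalued = TRUE),
    fixture_term("inducer compound", "observation unit", "curie", "optional",
                 definition = "Chemical compounds added as inducers.",
                 multivalued = TRUE),
    fixture_term("temperature setpoint", "observation unit", "decimal", "optional",
                 definition = "Cultivation temperature setpoint.",
                 object = "om:Temperature", unit = "degree Celsius"),
    fixture_term("data location", "observation unit", "url", "optional",
                 definition = "Where online data for analysis are stored."),
    fixture_term("sample volume", "sample", "decimal", "recommended",
                 definition = "Volume of culture withdrawn.",
                 object = "om:Volume", unit = "millilitre"),
    fixture_term("sampling time", "sample", "datetime", "optional",
                 definition = "ISO 8601 time of sampling."),
    fixture_term("source material", "sample", "string", "optional",
                 definition = "Source the sample was collected from."),
    fixture_term("optical density", "sample", "decimal", "optional",
                 definition = "OD600 at sampling."),
    fixture_term("assay type", "assay", "controlled", "mandatory",
                 allowed = c("hplc", "gc-ms", "od600"),
                 definition = "Analytical technique applied.",
                 object = "jerm:Assay"),
    fixture_term("data file", "assay", "url", "recommended",
                 definition = "Link to the raw data file."),
    fixture_term("operator email", "assay", "email", "optional",
                 definition = "Contact of the operator.")
  )
  mim_schema("MIFE_subset", levels, terms, FIXTURE_PREFIXES)
}

mifd_subset_schema <- function() {
  levels <- tibble::tibble(
    name = c("device", "vessel", "component"),
    description = c("Top layer of the cultivation equipment abstraction.",
                    "An individual fermentation unit hosted by a device.",
                    "Sensor or actuator attached to a vessel."),
    mapped_object = c(NA, NA, "obo:sosa_system"),
    extends = c(NA, NA, NA),
    parent_level = c(NA, "device", "vessel"),
    unit_column_present = c(FALSE, FALSE, FALSE)
  )
  terms <- rbind(
    fixture_term("device name", "device", "string", "mandatory",
                 definition = "Human-readable device name."),
    fixture_term("manufacturer", "device", "string", "recommended",
                 definition = "Device manufacturer."),
    fixture_term("device model", "device", "string", "optional",
                 definition = "Manufacturer model designation."),
    fixture_term("vessel type", "vessel", "controlled", "mandatory",
                 allowed = c("bioreactor", "microwell", "flask"),
                 definition = "Kind of fermentation vessel."),
    fixture_term("total volume", "vessel", "decimal", "optional",
                 definition = "Total vessel volume in litres."),
    fixture_term("component type", "component", "string", "mandatory",
                 definition = "Kind of sensor or actuator.",
                 object = "obo:sosa_sensor"),
    fixture_term("measured quantity", "component", "string", "optional",
                 definition = "Quantity the component measures.",
                 object = "om:Quantity")
  )
  mim_schema("MIFD_subset", levels, terms, FIXTURE_PREFIXES)
}

random_fixture_schema <- function(seed) {
  with_seed(seed, {
    n_levels <- sample(2:5, 1)
    lnames <- paste("tier", letters[seq_len(n_levels)])
    levels <- tibble::tibble(
      name = lnames,
      description = paste("Randomly drawn level", lnames),
      mapped_object = ifelse(stats::runif(n_levels) < 0.3,
                             paste0("obo:LVL_", seq_len(n_levels)), NA_character_),
      extends = NA_character_,
      parent_level = c(NA_character_, lnames[seq_len(n_levels - 1)]),
      unit_column_present = stats::runif(n_levels) < 0.5
    )
    kinds <- c("string", "text", "integer", "decimal", "boolean", "date",
               "datetime", "url", "email", "orcid", "curie", "controlled")
    terms <- empty_terms()
    tcount <- 0
    for (k in seq_len(n_levels)) {
      n_terms <- sample(2:6, 1)
      for (j in seq_len(n_terms)) {
        tcount <- tcount + 1
        kind <- sample(kinds, 1)
        allowed <- if (kind == "controlled") {
          sample(WORD_POOL, sample(2:4, 1))
        } else character(0)
        numeric_kind <- kind %in% c("integer", "decimal")
        terms <- rbind(terms, fixture_term(
          name = sprintf("term %02d %s", tcount, sample(WORD_POOL, 1)),
          level = lnames[k], syntax = kind,
          strictness = sample(STRICTNESS_VALUES, 1),
          allowed = allowed,
          definition = paste(sample(WORD_POOL, 3), collapse = " "),
          predicate = if (stats::runif(1) < 0.3) paste0("schema:p", tcount) else NA_character_,
          object = if (stats::runif(1) < 0.3) paste0("obo:T_", tcount) else NA_character_,
          multivalued = stats::runif(1) < 0.2,
          unit = if (numeric_kind && levels$unit_column_present[k] && stats::runif(1) < 0.5)
            sample(c("gram", "litre", "hour"), 1) else NA_character_
        ))
      }
    }
    mim_schema(sprintf("fixture_%d", seed), levels, terms, FIXTURE_PREFIXES)
  })
}

#' Generate a fixture schema
#'
#' @param profile "mife_subset" (5-level experiment chain), "mifd_subset"
#'   (3-level device chain) or "random" (seed-drawn chain for property
#'   tests)
#' @param seed integer seed (used by the random profile; recorded always)
#' @param path optional path to also write the schema workbook
#' @return list with `schema` (an `mim_schema`) and `manifest`
#' @export
make_fixture_schema <- function(profile = c("mife_subset", "mifd_subset", "random"),
                                seed = 1L, path = NULL) {
  profile <- match.arg(profile)
  schema <- switch(profile,
                   mife_subset = mife_subset_schema(),
                   mifd_subset = mifd_subset_schema(),
                   random = random_fixture_schema(seed))
  manifest <- list(
    profile = profile, seed = as.integer(seed),
    n_levels = nrow(schema$levels),
    levels = schema$levels$name,
    n_terms = nrow(schema$terms),
    n_terms_by_strictness = as.list(table(factor(schema$terms$strictness,
                                                 levels = STRICTNESS_VALUES))),
    n_mapped_terms = count_mapped_terms(schema)
  )
  if (!is.null(path)) write_schema_workbook(schema, path)
  list(schema = schema, manifest = manifest)
}

# one seeded valid token for a term definition
gen_token <- function(term_row, prefix_map) {
  word <- sample(WORD_POOL, 1)
  n <- sample(1:99, 1)
  switch(term_row$syntax,
    string = paste0(word, "-", n),
    text = paste(sample(WORD_POOL, 3), collapse = " "),
    integer = as.character(sample(0:500, 1)),
    decimal = {
      num <- sprintf("%.2f", stats::runif(1, 0, 100))
      if (!is.na(term_row$preferred_unit) && stats::runif(1) < 0.5) {
        paste(num, term_row$preferred_unit)
      } else num
    },
    boolean = sample(c("true", "false"), 1),
    date = sprintf("2025-%02d-%02d", sample(1:12, 1), sample(1:28, 1)),
    datetime = sprintf("2025-%02d-%02dT%02d:%02d:%02d",
                       sample(1:12, 1), sample(1:28, 1),
                       sample(0:23, 1), sample(0:59, 1), sample(0:59, 1)),
    url = sprintf("https://example.org/%s/%d", word, n),
    email = sprintf("%s%d@example.org", word, n),
    orcid = {
      base <- paste(sample(0:9, 15, replace = TRUE), collapse = "")
      full <- paste0(base, orcid_check_digit(base))
      paste(substring(full, c(1, 5, 9, 13), c(4, 8, 12, 16)), collapse = "-")
    },
    curie = sprintf("%s:%s_%d", sample(names(prefix_map), 1), toupper(word), n),
    controlled = sample(term_row$allowed_values[[1]], 1),
    stop_fermeta(sprintf("no generator for syntax '%s'", term_row$syntax),
                 "fermeta_fixture_error"))
}

VIOLATION_CYCLE <- c("MISSING_MANDATORY", "BAD_SYNTAX", "ORPHAN_RECORD",
                     "DUP_IDENTIFIER", "MULTIVALUE_ON_SINGLE")

#' Generate a filled fixture dataset, optionally with seeded violations
#'
#' Records are parent-consistent by construction (violations = 0 validates
#' cleanly). With violations = k, exactly k independent violations are
#' injected on distinct records — clearing a mandatory cell, corrupting a
#' typed token, breaking a parent reference, duplicating an identifier, or
#' appending a second token to a single-valued cell — and each is recorded
#' in the manifest, which is the oracle for recovery tests.
#'
#' @param schema a valid `mim_schema`
#' @param n_per_level named integer vector of record counts per level;
#'   defaults to 2–5 records per level
#' @param violations number of violations to inject (>= 0)
#' @param seed integer seed
#' @param path optional path to write the filled workbook
#' @return list with `dataset` (the in-memory `metadata_dataset`, mutations
#'   applied), `manifest`, and `path` when written
#' @export
make_fixture_dataset <- function(schema, n_per_level = NULL, violations = 0L,
                                 seed = 1L, path = NULL) {
  validate_mim_schema(schema)
  stopifnot(violations >= 0)
  lv <- schema$levels
  if (is.null(n_per_level)) {
    defaults <- c(2L, 3L, 3L, 4L, 5L)
    n_per_level <- stats::setNames(defaults[pmin(seq_len(nrow(lv)), 5)], lv$name)
  }
  with_seed(seed, {
    records <- empty_records()
    ids_by_level <- list()
    for (k in seq_len(nrow(lv))) {
      lname <- lv$name[k]
      n <- if (lname %in% names(n_per_level)) n_per_level[[lname]] else 0L
      if (n == 0) next
      tm <- terms_at(schema, lname)
      parent_ids <- if (!is.na(lv$parent_level[k]))
        ids_by_level[[norm_token(lv$parent_level[k])]] else NULL
      ids <- sprintf("%s-%d", gsub(" ", "-", norm_token(lname)), seq_len(n))
      ids_by_level[[norm_token(lname)]] <- ids
      for (i in seq_len(n)) {
        vals <- list()
        for (j in seq_len(nrow(tm))) {
          populate <- switch(tm$strictness[j], mandatory = TRUE,
                             recommended = TRUE, optional = stats::runif(1) < 0.7)
          if (!populate) next
          ntok <- if (tm$multivalued[j] && stats::runif(1) < 0.5) 2L else 1L
          vals[[tm$name[j]]] <- vapply(seq_len(ntok), function(x)
            gen_token(tm[j, ], schema$prefix_map), character(1))
        }
        records <- rbind(records, tibble::tibble(
          level = lname, identifier = ids[i],
          parent_identifier = if (is.null(parent_ids)) NA_character_
                              else sample(parent_ids, 1),
          values = list(vals)))
      }
    }

    # ---- violation injection ------------------------------------------
    has_children <- function(r) {
      any(!is.na(records$parent_identifier) &
            records$parent_identifier == records$identifier[r] &
            vapply(records$level, function(l)
              identical(norm_token(parent_of(schema, l) %||% ""),
                        norm_token(records$level[r])), logical(1)))
    }
    reserved <- rep(FALSE, nrow(records))
    manifest_viol <- list()
    mand_by_level <- lapply(stats::setNames(lv$name, norm_token(lv$name)),
                            function(l) terms_at(schema, l))
    candidates_for <- function(code) {
      out <- list()
      for (r in which(!reserved)) {
        tm <- mand_by_level[[norm_token(records$level[r])]]
        vals <- records$values[[r]]
        if (code == "MISSING_MANDATORY") {
          ts <- tm$name[tm$strictness == "mandatory" & tm$name %in% names(vals)]
          for (t in ts) out[[length(out) + 1]] <- list(r = r, term = t)
        } else if (code == "BAD_SYNTAX") {
          ts <- tm$name[!(tm$syntax %in% c("string", "text")) & tm$name %in% names(vals)]
          for (t in ts) out[[length(out) + 1]] <- list(r = r, term = t)
        } else if (code == "ORPHAN_RECORD") {
          if (!is.na(records$parent_identifier[r]) && !has_children(r)) {
            out[[length(out) + 1]] <- list(r = r, term = NA_character_)
          }
        } else if (code == "DUP_IDENTIFIER") {
          same <- which(norm_token(records$level) == norm_token(records$level[r]))
          donors <- setdiff(same[!reserved[same]], r)
          if (length(donors) > 0 && !has_children(r)) {
            out[[length(out) + 1]] <- list(r = r, term = NA_character_,
                                           donor = donors[1])
          }
        } else if (code == "MULTIVALUE_ON_SINGLE") {
          single <- tm$name[!tm$multivalued & tm$name %in% names(vals)]
          single <- single[vapply(single, function(t) length(vals[[t]]) == 1, logical(1))]
          for (t in single) out[[length(out) + 1]] <- list(r = r, term = t)
        }
      }
      out
    }
    ci <- 0L
    for (v in seq_len(violations)) {
      placed <- FALSE
      for (try in seq_along(VIOLATION_CYCLE)) {
        code <- VIOLATION_CYCLE[(ci + try - 1L) %% length(VIOLATION_CYCLE) + 1L]
        cand <- candidates_for(code)
        if (length(cand) == 0) next
        slot <- cand[[sample(length(cand), 1)]]
        r <- slot$r
        tm <- mand_by_level[[norm_token(records$level[r])]]
        vals <- records$values[[r]]
        if (code == "MISSING_MANDATORY") {
          vals[[slot$term]] <- NULL
        } else if (code == "BAD_SYNTAX") {
          vals[[slot$term]] <- "?not!a/value?"
        } else if (code == "ORPHAN_RECORD") {
          records$parent_identifier[r] <- "no-such-parent"
        } else if (code == "DUP_IDENTIFIER") {
          donor_id <- records$identifier[slot$donor]
          records$identifier[r] <- donor_id
          reserved[slot$donor] <- TRUE
        } else if (code == "MULTIVALUE_ON_SINGLE") {
          trow <- tm[tm$name == slot$term, ]
          vals[[slot$term]] <- c(vals[[slot$term]],
                                 gen_token(trow, schema$prefix_map))
        }
        records$values[[r]] <- vals
        reserved[r] <- TRUE
        manifest_viol[[length(manifest_viol) + 1]] <- list(
          code = code, level = records$level[r],
          identifier = records$identifier[r], term = slot$term)
        ci <- ci + try
        placed <- TRUE
        break
      }
      if (!placed) {
        stop_fermeta(sprintf("cannot place violation %d of %d: no free slots",
                             v, violations), "fermeta_fixture_error")
      }
    }

    dataset <- metadata_dataset(schema$name, records)
    manifest <- list(
      seed = as.integer(seed),
      schema = schema$name,
      n_records = nrow(records),
      n_records_by_level = as.list(table(factor(records$level, levels = lv$name))),
      n_violations = length(manifest_viol),
      violations = manifest_viol
    )
    if (!is.null(path)) write_filled_template(schema, dataset, path)
    list(dataset = dataset, manifest = manifest, path = path)
  })
}

#' Write a fixture manifest as JSON
#' @param manifest manifest list from a fixture generator
#' @param path output .json path
#' @return the path, invisibly
#' @export
write_fixture_manifest <- function(manifest, path) {
  txt <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, na = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}
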