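# Strictness-tiered dataset validation.
#
# Severity follows reporting tiers: a missing mandatory term is an error, a
# missing recommended term a warning, a missing optional term is silent.
# Structural checks (identifier uniqueness, parent resolution, token
# multiplicity, value syntax, units) are layered on top. Reports are
# deterministic: findings are sorted by (level order, identifier, term,
# code).

FINDING_CODES <- c(
  MISSING_MANDATORY = "error",
  MISSING_RECOMMENDED = "warning",
  BAD_SYNTAX = "error",
  UNKNOWN_TERM = "warning",
  UNKNOWN_LEVEL = "warning",
  ORPHAN_RECORD = "error",
  MULTIVALUE_ON_SINGLE = "error",
  UNIT_MISMATCH = "warning",
  DUP_IDENTIFIER = "error",
  MISSING_IDENTIFIER = "error",
  CROSS_REF_SKIPPED = "info",
  CROSS_REF_UNRESOLVED = "error"
)

empty_findings <- function() {
  tibble::tibble(severity = character(0), code = character(0),
                 level = character(0), identifier = character(0),
                 term = character(0), message = character(0))
}

finding <- function(code, level, identifier, term = NA_character_, message) {
  tibble::tibble(severity = unname(FINDING_CODES[[code]]), code = code,
                 level = level, identifier = identifier %||% NA_character_,
                 term = term, message = message)
}

#' Validate a metadata dataset against its schema
#'
#' @param schema the governing `mim_schema`
#' @param dataset a `metadata_dataset` parsed against the same schema
#' @param mifd_dataset optional co-loaded device (`MIFD`) dataset; when
#'   supplied, observation-unit terms naming a vessel are checked against
#'   the device dataset's vessel identifiers, otherwise that check is
#'   skipped with an info finding
#' @return a `validation_report`: findings tibble, per-severity counts and
#'   a pass flag (true iff zero errors)
#' @export
validate_dataset <- function(schema, dataset, mifd_dataset = NULL) {
  validate_mim_schema(schema)
  stopifnot(inherits(dataset, "metadata_dataset"))
  if (norm_token(dataset$schema_name) != norm_token(schema$name)) {
    stop_fermeta(sprintf("dataset was parsed against schema '%s', not '%s'",
                         dataset$schema_name, schema$name),
                 "fermeta_format_error")
  }
  findings <- empty_findings()
  add <- function(...) findings <<- rbind(findings, finding(...))
  recs <- dataset$records
  lv <- schema$levels
  decl <- norm_token(lv$name)
  vessel_ids <- NULL
  if (!is.null(mifd_dataset)) {
    vr <- mifd_dataset$records
    vessel_ids <- vr$identifier[norm_token(vr$level) == "vessel"]
  }

  ids_by_level <- split(recs$identifier, norm_token(recs$level))

  for (r in seq_len(nrow(recs))) {
    level <- recs$level[r]
    id <- recs$identifier[r]
    lkey <- norm_token(level)
    vals <- recs$values[[r]]
    if (!(lkey %in% decl)) {
      add("UNKNOWN_LEVEL", level, id,
          message = sprintf("sheet '%s' is not a level of schema '%s'",
                            level, schema$name))
      next
    }
    if (is.na(id) || !nzchar(id)) {
      add("MISSING_IDENTIFIER", level, id, message = "record has no identifier")
    } else {
      earlier <- which(norm_token(recs$level) == lkey & recs$identifier == id)
      if (earlier[1] < r) {
        add("DUP_IDENTIFIER", level, id,
            message = sprintf("identifier '%s' duplicated within level '%s'", id, level))
      }
    }
    parent_level <- parent_of(schema, level)
    if (!is.na(parent_level)) {
      pid <- recs$parent_identifier[r]
      parent_ids <- ids_by_level[[norm_token(parent_level)]] %||% character(0)
      # a record may also chain to a sibling at its own level (e.g. a
      # processed sample derived from another sample)
      sibling_ids <- setdiff(ids_by_level[[lkey]] %||% character(0), id)
      if (is.na(pid) || !nzchar(pid) ||
          !(pid %in% c(parent_ids, sibling_ids))) {
        add("ORPHAN_RECORD", level, id,
            message = sprintf("parent identifier '%s' does not name a %s record",
                              pid %||% "", parent_level))
      }
    }
    tm <- terms_at(schema, level)
    term_keys <- norm_token(tm$name)
    for (i in seq_len(nrow(tm))) {
      tname <- tm$name[i]
      toks <- NULL
      hit <- which(norm_token(names(vals)) == term_keys[i])
      if (length(hit) > 0) toks <- unlist(vals[hit], use.names = FALSE)
      if (is.null(toks) || length(toks) == 0) {
        if (tm$strictness[i] == "mandatory") {
          add("MISSING_MANDATORY", level, id, tname,
              sprintf("mandatory term '%s' is empty", tname))
        } else if (tm$strictness[i] == "recommended") {
          add("MISSING_RECOMMENDED", level, id, tname,
              sprintf("recommended term '%s' is empty", tname))
        }
        next
      }
      if (length(toks) > 1 && !tm$multivalued[i]) {
        add("MULTIVALUE_ON_SINGLE", level, id, tname,
            sprintf("term '%s' is single-valued but holds %d tokens", tname, length(toks)))
      }
      syn <- value_syntax(tm$syntax[i], tm$allowed_values[[i]])
      numeric_kind <- syn$kind %in% c("integer", "decimal")
      for (tok in toks) {
        check_tok <- tok
        if (numeric_kind) {
          parts <- split_unit_token(tok)
          if (!is.na(parts$unit)) {
            check_tok <- parts$value
            pref <- tm$preferred_unit[i]
            if (is.na(pref) || parts$unit != pref) {
              add("UNIT_MISMATCH", level, id, tname,
                  sprintf("unit '%s' differs from preferred unit '%s'",
                          parts$unit, pref %||% "(none)"))
            }
          }
        }
        if (!check_value_syntax(syn, check_tok, schema$prefix_map)) {
          add("BAD_SYNTAX", level, id, tname,
              sprintf("token '%s' does not match syntax '%s'",
                      tok, format_value_syntax(syn)))
        }
        # cross-schema vessel link on observation-unit records
        if (lkey == "observation unit" && grepl("vessel", term_keys[i]) &&
            syn$kind %in% c("curie", "string")) {
          if (is.null(vessel_ids)) {
            add("CROSS_REF_SKIPPED", level, id, tname,
                sprintf("vessel reference '%s' not checked (no device dataset loaded)", tok))
          } else if (!(tok %in% vessel_ids)) {
            add("CROSS_REF_UNRESOLVED", level, id, tname,
                sprintf("vessel reference '%s' names no vessel record", tok))
          }
        }
      }
    }
    unknown <- names(vals)[!(norm_token(names(vals)) %in% term_keys)]
    for (u in unknown) {
      add("UNKNOWN_TERM", level, id, u,
          sprintf("column '%s' is not a term of level '%s'", u, level))
    }
  }

  order_key <- order(match(norm_token(findings$level), c(decl, norm_token(findings$level))),
                     findings$identifier, findings$term, findings$code,
                     findings$message, na.last = FALSE)
  findings <- findings[order_key, , drop = FALSE]
  counts <- c(error = sum(findings$severity == "error"),
              warning = sum(findings$severity == "warning"),
              info = sum(findings$severity == "info"))
  structure(list(findings = findings, counts = counts,
                 pass = counts[["error"]] == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s), %d info\n",
              if (x$pass) "PASS" else "FAIL",
              x$counts[["error"]], x$counts[["warning"]], x$counts[["info"]]))
  if (nrow(x$findings)) {
    f <- x$findings
    for (i in seq_len(min(nrow(f), 50))) {
      cat(sprintf("  [%s] %s %s/%s%s: %s\n", f$severity[i], f$code[i],
                  f$level[i], f$identifier[i] %||% "?",
                  ifelse(is.na(f$term[i]), "", paste0(" (", f$term[i], ")")),
                  f$message[i]))
    }
    if (nrow(f) > 50) cat(sprintf("  ... and %d more\n", nrow(f) - 50))
  }
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' @param report a `validation_report`
#' @param path optional output path; when NULL the JSON string is returned
#' @return JSON string (invisibly when written to a file)
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  obj <- list(report_version = 1L,
              pass = report$pass,
              counts = as.list(report$counts),
              findings = report$findings)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null", pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
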