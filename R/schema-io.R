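# Reader/writer for the spreadsheet schema dialect.
#
# A schema workbook has a "metadata_levels" sheet (one row per hierarchical
# level: metadata level / description / object / extends, optionally
# parent level) and one sheet per level (one row per term: term / metadata
# level / value syntax / definition / example / strictness / predicate /
# object / multivalued, plus preferred unit on unit-tracking levels).
# Header and sheet-name matching is normalised (case, whitespace,
# underscores); column order is irrelevant; unknown columns are preserved
# as opaque per-term annotations.

LEVELS_SHEET <- "metadata_levels"

get_col <- function(df, header) {
  i <- match(norm_token(header), norm_token(names(df)))
  if (is.na(i)) return(NULL)
  v <- trimws(as.character(df[[i]]))
  v[!nzchar(v) | is.na(v)] <- NA_character_
  v
}

parse_multivalued <- function(x, sheet) {
  out <- rep(FALSE, length(x))
  tok <- norm_token(x)
  out[tok %in% c("true", "yes", "1", "y")] <- TRUE
  bad <- !is.na(x) & !(tok %in% c("true", "yes", "1", "y", "false", "no", "0", "n"))
  if (any(bad)) {
    stop_fermeta(sprintf("sheet '%s': unrecognised multivalued token(s): %s",
                         sheet, paste(unique(x[bad]), collapse = ", ")),
                 "fermeta_schema_error")
  }
  out
}

KNOWN_TERM_HEADERS <- c("term", "metadata level", "value syntax", "definition",
                        "example", "strictness", "predicate", "object",
                        "multivalued", "preferred unit")

#' Read a schema workbook
#'
#' @param path workbook path
#' @param name schema name; defaults to the file stem. Names containing
#'   "MIFE"/"MIFD" (or workbooks whose level set equals one of those models)
#'   get the fixed experiment/device hierarchy; otherwise an optional
#'   "parent level" column in metadata_levels defines the hierarchy.
#' @param prefix_map named character vector (prefix -> IRI base) merged over
#'   any "prefixes" sheet present in the workbook
#' @return an `mim_schema`
#' @export
read_schema_workbook <- function(path, name = NULL, prefix_map = character(0)) {
  name <- name %||% tools::file_path_sans_ext(basename(path))
  sheets <- read_xlsx_sheets(path)
  sheet_keys <- norm_token(names(sheets))
  sheet_idx <- function(key) {
    i <- match(norm_token(key), sheet_keys)
    if (is.na(i)) NULL else i
  }
  li <- sheet_idx(LEVELS_SHEET)
  if (is.null(li)) {
    stop_fermeta(sprintf("workbook has no '%s' sheet", LEVELS_SHEET),
                 "fermeta_format_error")
  }
  lvdf <- sheets[[li]]
  level_names <- get_col(lvdf, "metadata level") %||% character(0)
  level_names <- level_names[!is.na(level_names)]
  levels <- tibble::tibble(
    name = level_names,
    description = (get_col(lvdf, "description") %||% rep(NA_character_, length(level_names)))[seq_along(level_names)],
    mapped_object = (get_col(lvdf, "object") %||% rep(NA_character_, length(level_names)))[seq_along(level_names)],
    extends = (get_col(lvdf, "extends") %||% rep(NA_character_, length(level_names)))[seq_along(level_names)],
    parent_level = (get_col(lvdf, "parent level") %||% rep(NA_character_, length(level_names)))[seq_along(level_names)],
    unit_column_present = FALSE
  )
  levels <- resolve_hierarchy(name, levels)

  terms <- empty_terms()
  for (k in seq_len(nrow(levels))) {
    lname <- levels$name[k]
    si <- sheet_idx(lname)
    if (is.null(si)) {
      stop_fermeta(sprintf("level '%s' declared in %s but has no sheet",
                           lname, LEVELS_SHEET), "fermeta_format_error")
    }
    df <- sheets[[si]]
    has_unit_col <- !is.na(match(norm_token("preferred unit"), norm_token(names(df))))
    levels$unit_column_present[k] <- has_unit_col
    tnames <- get_col(df, "term")
    if (is.null(tnames)) {
      if (nrow(df) == 0) next
      stop_fermeta(sprintf("sheet '%s' has no 'term' column", lname),
                   "fermeta_format_error")
    }
    keep <- which(!is.na(tnames))
    if (length(keep) == 0) next
    n <- nrow(df)
    pull <- function(h) (get_col(df, h) %||% rep(NA_character_, n))[keep]
    syn_tokens <- pull("value syntax")
    strict <- pull("strictness")
    if (anyNA(syn_tokens)) {
      stop_fermeta(sprintf("sheet '%s': missing value syntax for term(s) %s",
                           lname, paste(tnames[keep][is.na(syn_tokens)], collapse = ", ")),
                   "fermeta_schema_error")
    }
    if (anyNA(strict)) {
      stop_fermeta(sprintf("sheet '%s': missing strictness in row(s) %s",
                           lname, paste(which(is.na(strict)), collapse = ", ")),
                   "fermeta_schema_error")
    }
    bad_strict <- !(norm_token(strict) %in% STRICTNESS_VALUES)
    if (any(bad_strict)) {
      stop_fermeta(sprintf("sheet '%s': unknown strictness token(s) in row(s) %s: %s",
                           lname,
                           paste(keep[bad_strict] + 1, collapse = ", "),
                           paste(unique(strict[bad_strict]), collapse = ", ")),
                   "fermeta_schema_error")
    }
    syn <- lapply(syn_tokens, parse_value_syntax)
    term_level <- pull("metadata level")
    term_level[is.na(term_level)] <- lname
    mismatch <- norm_token(term_level) != norm_token(lname)
    if (any(mismatch)) {
      stop_fermeta(sprintf("sheet '%s': term(s) declare a different metadata level: %s",
                           lname, paste(tnames[keep][mismatch], collapse = ", ")),
                   "fermeta_schema_error")
    }
    extra_cols <- names(df)[!(norm_token(names(df)) %in% norm_token(KNOWN_TERM_HEADERS)) &
                              nzchar(names(df))]
    extras <- lapply(keep, function(i) {
      if (length(extra_cols) == 0) return(NULL)
      vals <- vapply(extra_cols, function(cn) {
        v <- trimws(as.character(df[[cn]][i]))
        if (is.na(v) || !nzchar(v)) NA_character_ else v
      }, character(1))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) NULL else vals
    })
    terms <- rbind(terms, tibble::tibble(
      name = tnames[keep],
      level = rep(lname, length(keep)),
      syntax = vapply(syn, function(s) s$kind, character(1)),
      allowed_values = lapply(syn, function(s) s$allowed_values),
      definition = pull("definition"),
      example = pull("example"),
      strictness = norm_token(strict),
      predicate = pull("predicate"),
      mapped_object = pull("object"),
      multivalued = parse_multivalued(pull("multivalued"), lname),
      preferred_unit = if (has_unit_col) pull("preferred unit") else rep(NA_character_, length(keep)),
      extra = extras
    ))
  }

  pm_idx <- sheet_idx("prefixes")
  if (!is.null(pm_idx)) {
    pdf <- sheets[[pm_idx]]
    pfx <- get_col(pdf, "prefix")
    iri <- get_col(pdf, "iri")
    if (!is.null(pfx) && !is.null(iri)) {
      keep <- !is.na(pfx) & !is.na(iri)
      wb_map <- stats::setNames(iri[keep], pfx[keep])
      prefix_map <- c(wb_map[!(names(wb_map) %in% names(prefix_map))], prefix_map)
    }
  }
  mim_schema(name = name, levels = levels, terms = terms, prefix_map = prefix_map)
}

#' Write a schema to a workbook in the spreadsheet dialect
#'
#' Produces a workbook that [read_schema_workbook()] parses back into an
#' equal schema (round-trip identity on every field, including hierarchy,
#' multivalued flags, preferred units and the prefix map).
#'
#' @param schema a valid `mim_schema`
#' @param path output .xlsx path
#' @return the path, invisibly
#' @export
write_schema_workbook <- function(schema, path) {
  validate_mim_schema(schema)
  lv <- schema$levels
  sheets <- list()
  sheets[[LEVELS_SHEET]] <- data.frame(
    `metadata level` = lv$name,
    description = lv$description,
    object = lv$mapped_object,
    extends = lv$extends,
    `parent level` = lv$parent_level,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(lv))) {
    tm <- terms_at(schema, lv$name[k])
    df <- data.frame(
      term = tm$name,
      `metadata level` = tm$level,
      `value syntax` = vapply(seq_len(nrow(tm)), function(i) {
        format_value_syntax(value_syntax(tm$syntax[i], tm$allowed_values[[i]]))
      }, character(1)),
      definition = tm$definition,
      example = tm$example,
      strictness = tm$strictness,
      predicate = tm$predicate,
      object = tm$mapped_object,
      multivalued = ifelse(tm$multivalued, "true", "false"),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    if (nrow(tm) == 0) {
      df <- data.frame(term = character(0), `metadata level` = character(0),
                       `value syntax` = character(0), definition = character(0),
                       example = character(0), strictness = character(0),
                       predicate = character(0), object = character(0),
                       multivalued = character(0),
                       check.names = FALSE, stringsAsFactors = FALSE)
    }
    if (lv$unit_column_present[k]) {
      df[["preferred unit"]] <- if (nrow(tm)) tm$preferred_unit else character(0)
    }
    extra_names <- unique(unlist(lapply(tm$extra, names)))
    for (en in extra_names) {
      df[[en]] <- vapply(tm$extra, function(e) e[[en]] %||% NA_character_, character(1))
    }
    sheets[[lv$name[k]]] <- df
  }
  if (length(schema$prefix_map) > 0) {
    sheets[["prefixes"]] <- data.frame(prefix = names(schema$prefix_map),
                                       iri = unname(schema$prefix_map),
                                       check.names = FALSE, stringsAsFactors = FALSE)
  }
  write_xlsx_sheets(sheets, path)
}

#' Read a prefix map from a YAML or JSON file
#'
#' @param path file with a flat mapping prefix -> IRI base
#' @return named character vector
#' @export
read_prefix_map <- function(path) {
  if (!file.exists(path)) {
    stop_fermeta(sprintf("prefix map not found: %s", path), "fermeta_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(raw) == 0) return(character(0))
  out <- vapply(raw, as.character, character(1))
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop_fermeta("prefix map must be a named mapping", "fermeta_format_error")
  }
  out
}
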