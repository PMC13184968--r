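# Template generation and parsing of filled metadata workbooks.
#
# A template has one sheet per metadata level. The header row holds the
# identifier column, a parent-identifier column on non-root levels, then
# the level's term names in schema order. A second annotation row (first
# cell "#strictness") marks each term column's reporting tier; the parser
# tolerates and skips it, so a template parses back as an empty dataset.

ID_HEADER <- "identifier"
PARENT_HEADER <- "parent identifier"
ANNOTATION_MARK <- "#strictness"

#' Generate a fill-in metadata template for a schema
#'
#' @param schema a valid `mim_schema`
#' @param path output .xlsx path
#' @return the path, invisibly
#' @export
generate_template <- function(schema, path) {
  validate_mim_schema(schema)
  lv <- schema$levels
  if (nrow(lv) == 0) {
    # no level sheets; a bare placeholder keeps the workbook readable
    return(write_xlsx_sheets(list(about = data.frame(
      schema = schema$name, levels = "0", check.names = FALSE)), path))
  }
  sheets <- list()
  for (k in seq_len(nrow(lv))) {
    tm <- terms_at(schema, lv$name[k])
    headers <- c(ID_HEADER,
                 if (!is.na(lv$parent_level[k])) PARENT_HEADER,
                 tm$name)
    annot <- c(ANNOTATION_MARK,
               if (!is.na(lv$parent_level[k])) "required",
               tm$strictness)
    df <- as.data.frame(rbind(annot), stringsAsFactors = FALSE)
    names(df) <- headers
    sheets[[lv$name[k]]] <- df
  }
  write_xlsx_sheets(sheets, path)
}

empty_records <- function() {
  tibble::tibble(level = character(0), identifier = character(0),
                 parent_identifier = character(0), values = list())
}

#' Construct a metadata dataset
#' @param schema_name schema name token
#' @param records tibble with columns level / identifier /
#'   parent_identifier / values (named list of character token vectors)
#' @param extra_levels character vector of sheet names seen in a workbook
#'   but not declared by the schema
#' @return a `metadata_dataset`
#' @export
metadata_dataset <- function(schema_name, records = empty_records(),
                             extra_levels = character(0)) {
  records <- tibble::as_tibble(records)
  structure(list(schema_name = schema_name, records = records,
                 extra_levels = extra_levels),
            class = "metadata_dataset")
}

#' @export
print.metadata_dataset <- function(x, ...) {
  cat(sprintf("<metadata_dataset> %s: %d record(s) across %d level(s)\n",
              x$schema_name, nrow(x$records), length(unique(x$records$level))))
  invisible(x)
}

split_cell <- function(cell) {
  if (is.na(cell)) return(character(0))
  toks <- trimws(strsplit(as.character(cell), "|", fixed = TRUE)[[1]])
  toks[nzchar(toks)]
}

#' Parse a filled metadata workbook into a dataset
#'
#' One record per non-empty data row; cells are split on "|" with
#' whitespace trimmed; blank cells are absent from the value map. Sheets
#' not declared by the schema are parsed too and flagged at validation.
#'
#' @param schema the `mim_schema` the template was generated from
#' @param path filled workbook path
#' @return a `metadata_dataset`
#' @export
parse_filled_template <- function(schema, path) {
  validate_mim_schema(schema)
  sheets <- read_xlsx_sheets(path)
  declared <- stats::setNames(schema$levels$name, norm_token(schema$levels$name))
  records <- empty_records()
  extra_levels <- character(0)
  for (s in names(sheets)) {
    skey <- norm_token(s)
    if (skey %in% c("about", "prefixes")) next
    level <- if (skey %in% names(declared)) declared[[skey]] else {
      extra_levels <- c(extra_levels, s)
      s
    }
    df <- sheets[[s]]
    if (nrow(df) == 0 || ncol(df) == 0) next
    hdr_norm <- norm_token(names(df))
    id_col <- match(norm_token(ID_HEADER), hdr_norm)
    parent_col <- match(norm_token(PARENT_HEADER), hdr_norm)
    term_cols <- setdiff(seq_along(df), c(id_col, parent_col))
    term_cols <- term_cols[nzchar(names(df)[term_cols])]
    for (i in seq_len(nrow(df))) {
      row <- vapply(seq_along(df), function(j) {
        v <- df[[j]][i]
        if (is.na(v)) NA_character_ else trimws(as.character(v))
      }, character(1))
      row[!is.na(row) & !nzchar(row)] <- NA_character_
      if (!is.na(id_col) && identical(row[id_col], ANNOTATION_MARK)) next
      if (all(is.na(row))) next
      values <- list()
      for (j in term_cols) {
        toks <- split_cell(row[j])
        if (length(toks) > 0) values[[names(df)[j]]] <- toks
      }
      records <- rbind(records, tibble::tibble(
        level = level,
        identifier = if (!is.na(id_col)) row[id_col] %||% NA_character_ else NA_character_,
        parent_identifier = if (!is.na(parent_col)) row[parent_col] else NA_character_,
        values = list(values)))
    }
  }
  metadata_dataset(schema$name, records, unique(extra_levels))
}

#' Write a metadata dataset as a filled workbook
#'
#' Inverse of [parse_filled_template()]: produces a workbook in template
#' layout (annotation row included) holding the dataset's records.
#'
#' @param schema the governing `mim_schema`
#' @param dataset a `metadata_dataset`
#' @param path output .xlsx path
#' @return the path, invisibly
#' @export
write_filled_template <- function(schema, dataset, path) {
  validate_mim_schema(schema)
  lv <- schema$levels
  sheets <- list()
  for (k in seq_len(nrow(lv))) {
    lname <- lv$name[k]
    tm <- terms_at(schema, lname)
    has_parent <- !is.na(lv$parent_level[k])
    headers <- c(ID_HEADER, if (has_parent) PARENT_HEADER, tm$name)
    recs <- dataset$records[norm_token(dataset$records$level) == norm_token(lname), , drop = FALSE]
    rows <- list(c(ANNOTATION_MARK, if (has_parent) "required", tm$strictness))
    for (i in seq_len(nrow(recs))) {
      vals <- recs$values[[i]]
      cells <- vapply(tm$name, function(t) {
        toks <- vals[[t]]
        if (is.null(toks) || length(toks) == 0) NA_character_
        else paste(toks, collapse = " | ")
      }, character(1))
      rows[[length(rows) + 1]] <- c(recs$identifier[i],
                                    if (has_parent) recs$parent_identifier[i],
                                    cells)
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- headers
    sheets[[lname]] <- df
  }
  if (length(sheets) == 0) {
    sheets[["about"]] <- data.frame(schema = schema$name, check.names = FALSE)
  }
  write_xlsx_sheets(sheets, path)
}
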