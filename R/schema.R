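# In-memory model of a minimum-information schema.
#
# A schema is an ordered set of hierarchical metadata levels (investigation,
# study, observation unit, sample, assay for experiments; device, vessel,
# component for devices) plus term definitions. Each term carries a value
# syntax, a strictness tier (mandatory / recommended / optional), optional
# ontology mappings (predicate / object CURIEs), a multivalued flag, and —
# on levels that track measurement units — a preferred unit.

STRICTNESS_VALUES <- c("mandatory", "recommended", "optional")

SYNTAX_KINDS <- c("string", "text", "integer", "decimal", "boolean", "date",
                  "datetime", "url", "email", "orcid", "curie", "controlled")

# Fixed level hierarchies (the spreadsheet dialect carries no parent column
# for these named models; their chains are part of the model definitions).
KNOWN_HIERARCHIES <- list(
  mife = c("investigation", "study", "observation unit", "sample", "assay"),
  mifd = c("device", "vessel", "component")
)

#' Parse a strictness token
#'
#' Case-insensitive; exactly "mandatory", "recommended" or "optional".
#' @param x character token(s)
#' @return normalised strictness value(s)
#' @export
parse_strictness <- function(x) {
  v <- norm_token(x)
  bad <- !(v %in% STRICTNESS_VALUES)
  if (any(bad)) {
    stop_fermeta(sprintf("unknown strictness token(s): %s",
                         paste(unique(x[bad]), collapse = ", ")),
                 "fermeta_schema_error")
  }
  v
}

#' Construct a value syntax
#'
#' @param kind one of `SYNTAX_KINDS`
#' @param allowed_values character vector of permitted tokens; required for
#'   (and only for) kind "controlled"
#' @return a `value_syntax` object
#' @export
value_syntax <- function(kind, allowed_values = character(0)) {
  kind <- norm_token(kind)
  if (!kind %in% SYNTAX_KINDS) {
    stop_fermeta(sprintf("unknown value syntax kind: %s", kind),
                 "fermeta_schema_error")
  }
  allowed_values <- as.character(allowed_values)
  if (kind == "controlled" && length(allowed_values) == 0) {
    stop_fermeta("controlled syntax requires non-empty allowed_values",
                 "fermeta_schema_error")
  }
  if (kind != "controlled" && length(allowed_values) > 0) {
    stop_fermeta(sprintf("syntax kind '%s' does not take allowed values", kind),
                 "fermeta_schema_error")
  }
  structure(list(kind = kind, allowed_values = allowed_values),
            class = "value_syntax")
}

#' Parse a value-syntax cell token
#'
#' Plain kinds are their own token ("integer", "orcid", ...); enumerations
#' are written "controlled:\{a|b|c\}".
#' @param x cell token
#' @return a `value_syntax`
#' @export
parse_value_syntax <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^controlled[[:space:]]*:[[:space:]]*\\{(.*)\\}$",
                             x, ignore.case = TRUE))[[1]]
  if (length(m) == 2) {
    vals <- trimws(strsplit(m[2], "|", fixed = TRUE)[[1]])
    vals <- vals[nzchar(vals)]
    return(value_syntax("controlled", vals))
  }
  value_syntax(x)
}

#' Serialise a value syntax back to its cell token
#' @param syntax a `value_syntax`
#' @return character token
#' @export
format_value_syntax <- function(syntax) {
  syntax <- as_value_syntax(syntax)
  if (syntax$kind == "controlled") {
    sprintf("controlled:{%s}", paste(syntax$allowed_values, collapse = "|"))
  } else {
    syntax$kind
  }
}

as_value_syntax <- function(x) {
  if (inherits(x, "value_syntax")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_value_syntax(x))
  if (is.list(x) && !is.null(x$kind)) {
    return(value_syntax(x$kind, x$allowed_values %||% character(0)))
  }
  stop_fermeta("cannot interpret object as a value syntax", "fermeta_schema_error")
}

empty_levels <- function() {
  tibble::tibble(name = character(0), description = character(0),
                 mapped_object = character(0), extends = character(0),
                 parent_level = character(0), unit_column_present = logical(0))
}

empty_terms <- function() {
  tibble::tibble(name = character(0), level = character(0),
                 syntax = character(0), allowed_values = list(),
                 definition = character(0), example = character(0),
                 strictness = character(0), predicate = character(0),
                 mapped_object = character(0), multivalued = logical(0),
                 preferred_unit = character(0), extra = list())
}

#' Construct a minimum-information schema
#'
#' @param name schema name token (e.g. "MIFE")
#' @param levels tibble of metadata levels (see [empty_levels()] columns)
#' @param terms tibble of term definitions (see [empty_terms()] columns)
#' @param prefix_map named character vector, prefix -> IRI base
#' @return validated `mim_schema` object
#' @export
mim_schema <- function(name, levels = empty_levels(), terms = empty_terms(),
                       prefix_map = character(0)) {
  levels <- tibble::as_tibble(levels)
  terms <- tibble::as_tibble(terms)
  for (col in names(empty_levels())) {
    if (!col %in% names(levels)) {
      levels[[col]] <- if (col == "unit_column_present") logical(nrow(levels)) else rep(NA_character_, nrow(levels))
    }
  }
  for (col in names(empty_terms())) {
    if (!col %in% names(terms)) {
      terms[[col]] <- switch(col,
        multivalued = logical(nrow(terms)),
        allowed_values = rep(list(character(0)), nrow(terms)),
        extra = rep(list(NULL), nrow(terms)),
        rep(NA_character_, nrow(terms)))
    }
  }
  levels <- levels[, names(empty_levels())]
  terms <- terms[, names(empty_terms())]
  # normalise column types (all-NA columns default to logical in R)
  for (col in setdiff(names(levels), "unit_column_present")) {
    levels[[col]] <- as.character(levels[[col]])
  }
  levels$unit_column_present <- as.logical(levels$unit_column_present)
  for (col in setdiff(names(terms), c("allowed_values", "extra", "multivalued"))) {
    terms[[col]] <- as.character(terms[[col]])
  }
  terms$multivalued <- as.logical(terms$multivalued)
  schema <- structure(list(name = as.character(name), levels = levels,
                           terms = terms,
                           prefix_map = prefix_map),
                      class = "mim_schema")
  validate_mim_schema(schema)
  schema
}

#' Validate schema invariants
#'
#' Checks level-name uniqueness, term/(level) uniqueness, that every term's
#' level is declared, that parent edges form a forest (no cycles, parents
#' exist), strictness and syntax validity, and that preferred units only
#' occur on levels carrying a unit column.
#' @param schema an `mim_schema`
#' @return the schema, invisibly; errors on violation
#' @export
validate_mim_schema <- function(schema) {
  stopifnot(inherits(schema, "mim_schema"))
  lv <- schema$levels
  tm <- schema$terms
  if (anyDuplicated(norm_token(lv$name))) {
    stop_fermeta("duplicate level names (case-insensitive)", "fermeta_schema_error")
  }
  key <- paste(norm_token(tm$level), norm_token(tm$name), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tm[duplicated(key), , drop = FALSE]
    stop_fermeta(sprintf("duplicate (term, level) pair(s): %s",
                         paste(sprintf("'%s'@'%s'", dup$name, dup$level), collapse = ", ")),
                 "fermeta_schema_error")
  }
  unknown <- !(norm_token(tm$level) %in% norm_token(lv$name))
  if (any(unknown)) {
    stop_fermeta(sprintf("term(s) reference undeclared level(s): %s",
                         paste(unique(tm$level[unknown]), collapse = ", ")),
                 "fermeta_schema_error")
  }
  parse_strictness(tm$strictness)
  lapply(seq_len(nrow(tm)), function(i) {
    value_syntax(tm$syntax[i], tm$allowed_values[[i]])
  })
  # parent edges: must name declared levels and contain no cycle
  pmap <- stats::setNames(lv$parent_level, norm_token(lv$name))
  set_parents <- !is.na(lv$parent_level)
  if (any(set_parents)) {
    missing_parent <- !(norm_token(lv$parent_level[set_parents]) %in% norm_token(lv$name))
    if (any(missing_parent)) {
      stop_fermeta(sprintf("parent level(s) not declared: %s",
                           paste(unique(lv$parent_level[set_parents][missing_parent]),
                                 collapse = ", ")), "fermeta_schema_error")
    }
    for (start in norm_token(lv$name)) {
      seen <- character(0)
      cur <- start
      while (!is.na(cur)) {
        if (cur %in% seen) {
          stop_fermeta(sprintf("level hierarchy contains a cycle through '%s'", cur),
                       "fermeta_schema_error")
        }
        seen <- c(seen, cur)
        nxt <- pmap[[cur]]
        cur <- if (is.null(nxt) || is.na(nxt)) NA_character_ else norm_token(nxt)
      }
    }
  }
  unit_ok <- stats::setNames(lv$unit_column_present, norm_token(lv$name))
  has_unit <- !is.na(tm$preferred_unit)
  if (any(has_unit)) {
    bad <- !unit_ok[norm_token(tm$level[has_unit])]
    if (any(bad)) {
      stop_fermeta(sprintf("preferred unit set on term(s) of level(s) without a unit column: %s",
                           paste(unique(tm$level[has_unit][bad]), collapse = ", ")),
                   "fermeta_schema_error")
    }
  }
  invisible(schema)
}

#' Root levels of a schema (levels with no parent)
#' @keywords internal
root_levels <- function(schema) {
  schema$levels$name[is.na(schema$levels$parent_level)]
}

#' Parent level of a given level (NA for roots)
#' @keywords internal
parent_of <- function(schema, level) {
  i <- match(norm_token(level), norm_token(schema$levels$name))
  if (is.na(i)) NA_character_ else schema$levels$parent_level[i]
}

#' Terms declared at one level, in schema order
#' @keywords internal
terms_at <- function(schema, level) {
  schema$terms[norm_token(schema$terms$level) == norm_token(level), , drop = FALSE]
}

#' Count ontology-mapped terms
#'
#' Number of term definitions whose "object" column (mapping to an existing
#' knowledge organisation system) is non-empty. For the full published MIFE
#' and MIFD workbooks these counts are 89 and 26 respectively.
#'
#' @param schema an `mim_schema`
#' @return integer count
#' @export
count_mapped_terms <- function(schema) {
  sum(!is.na(schema$terms$mapped_object) & nzchar(schema$terms$mapped_object))
}

#' @export
print.mim_schema <- function(x, ...) {
  cat(sprintf("<mim_schema> %s: %d level(s), %d term(s), %d mapped to KOS\n",
              x$name, nrow(x$levels), nrow(x$terms), count_mapped_terms(x)))
  if (nrow(x$levels)) {
    cat("  levels:", paste(x$levels$name, collapse = " > "), "\n")
  }
  invisible(x)
}

#' Resolve the level hierarchy for a schema read from a workbook
#'
#' Precedence: an explicit "parent level" column; else the fixed chains of
#' the named MIFE/MIFD models (matched by schema name or by the exact level
#' set); else a flat forest of roots.
#' @keywords internal
resolve_hierarchy <- function(name, levels) {
  if (nrow(levels) == 0) return(levels)
  if (any(!is.na(levels$parent_level))) return(levels)
  chain <- NULL
  nm <- norm_token(name)
  lv <- norm_token(levels$name)
  for (model in names(KNOWN_HIERARCHIES)) {
    hier <- KNOWN_HIERARCHIES[[model]]
    if (grepl(model, nm, fixed = TRUE) || setequal(lv, hier)) {
      chain <- hier
      break
    }
  }
  if (is.null(chain)) return(levels)
  idx <- match(lv, chain)
  parent <- ifelse(is.na(idx) | idx == 1, NA_character_, chain[pmax(idx - 1, 1)])
  # map normalised parent names back to declared spelling
  back <- stats::setNames(levels$name, lv)
  levels$parent_level <- ifelse(is.na(parent), NA_character_, unname(back[parent]))
  levels
}
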