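# Pure value-syntax predicates used by the validator.

#' ISO 7064 mod 11-2 check digit for an ORCID base
#'
#' @param digits15 character string of the 15 base digits (hyphens stripped)
#' @return the check character, "0".."9" or "X"
#' @export
orcid_check_digit <- function(digits15) {
  d <- as.integer(strsplit(gsub("-", "", digits15), "")[[1]])
  stopifnot(length(d) == 15, !anyNA(d))
  total <- 0L
  for (x in d) total <- (total + x) * 2L
  result <- (12L - (total %% 11L)) %% 11L
  if (result == 10L) "X" else as.character(result)
}

orcid_ok <- function(token) {
  if (!grepl("^\\d{4}-\\d{4}-\\d{4}-\\d{3}[0-9X]$", token)) return(FALSE)
  digits <- gsub("-", "", token)
  substr(digits, 16, 16) == orcid_check_digit(substr(digits, 1, 15))
}

iso_date_ok <- function(token) {
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", token)) return(FALSE)
  !is.na(as.Date(token, format = "%Y-%m-%d", optional = TRUE))
}

iso_datetime_ok <- function(token) {
  re <- paste0("^(\\d{4}-\\d{2}-\\d{2})[T ]",
               "(\\d{2}):(\\d{2})(:\\d{2}(\\.\\d+)?)?",
               "(Z|[+-]\\d{2}:?\\d{2})?$")
  m <- regmatches(token, regexec(re, token))[[1]]
  if (length(m) == 0) return(FALSE)
  if (!iso_date_ok(m[2])) return(FALSE)
  as.integer(m[3]) < 24 && as.integer(m[4]) < 60
}

#' Check a raw cell token against a value syntax
#'
#' A pure predicate: no findings, no side effects. Dates and datetimes are
#' ISO 8601; ORCIDs must match the 4x4 hyphenated pattern and pass the
#' ISO 7064 mod 11-2 checksum; CURIEs must use a declared prefix when a
#' prefix map is supplied; controlled values are matched case-sensitively.
#'
#' @param syntax a `value_syntax` (or a syntax cell token such as "integer"
#'   or "controlled:\{a|b\}")
#' @param token raw cell token (already trimmed, single value)
#' @param prefix_map named character vector of declared CURIE prefixes;
#'   when empty, CURIE checking is syntactic only
#' @return TRUE or FALSE
#' @export
check_value_syntax <- function(syntax, token, prefix_map = character(0)) {
  syntax <- as_value_syntax(syntax)
  token <- as.character(token)
  if (length(token) != 1 || is.na(token)) return(FALSE)
  switch(syntax$kind,
    string = nzchar(token),
    text = nzchar(token),
    integer = grepl("^[+-]?[0-9]+$", token),
    decimal = grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$", token),
    boolean = tolower(token) %in% c("true", "false"),
    date = iso_date_ok(token),
    datetime = iso_datetime_ok(token),
    url = grepl("^[A-Za-z][A-Za-z0-9+.-]*://[^[:space:]]+$", token),
    email = grepl("^[^@[:space:]]+@[^@[:space:]]+$", token),
    orcid = orcid_ok(token),
    curie = {
      m <- regmatches(token, regexec("^([A-Za-z_][A-Za-z0-9._-]*):([^[:space:]]*)$", token))[[1]]
      if (length(m) == 0) FALSE
      else if (length(prefix_map) > 0) m[2] %in% names(prefix_map)
      else TRUE
    },
    controlled = token %in% syntax$allowed_values,
    FALSE)
}

# Split "<number> <unit>" into value and unit parts; unit NA when absent.
split_unit_token <- function(token) {
  m <- regmatches(token, regexec(
    "^([+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?)[[:space:]]+(\\S.*)$",
    token))[[1]]
  if (length(m) == 0) list(value = token, unit = NA_character_)
  else list(value = m[2], unit = trimws(m[6]))
}
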