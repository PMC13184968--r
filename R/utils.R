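#' fermeta: schema engine for fermentation minimum-information metadata
#'
#' Reads spreadsheet-defined minimum-information schemas, compiles them to
#' LinkML-dialect YAML, generates and validates metadata templates, exports
#' validated metadata to RDF, and builds Common Provenance Model backbones.
#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || all(is.na(x))) y else x

#' Normalise a header or sheet-name token
#'
#' Lowercases, trims, and collapses internal whitespace/underscores so that
#' hand-edited spreadsheet headers like "Value Syntax" or "value_syntax"
#' match the canonical "value syntax".
#' @param x character vector
#' @return normalised character vector
#' @keywords internal
norm_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]_]+", " ", x)
}

#' Slug-case a name (lowercase, underscores)
#' @keywords internal
slugify <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Slug for IRI path segments (hyphens)
#' @keywords internal
iri_slug <- function(x) gsub("_", "-", slugify(x))

# scalar-or-NA coalescing of a possibly-missing cell
cell_or_na <- function(x) {
  if (is.null(x) || length(x) == 0) return(NA_character_)
  x <- trimws(as.character(x[[1]]))
  if (is.na(x) || !nzchar(x)) NA_character_ else x
}

is_blank <- function(x) is.na(x) | !nzchar(trimws(x))

#' Run code with a temporarily fixed RNG seed, restoring global state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_fermeta <- function(msg, class) {
  stop(structure(class = c(class, "fermeta_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
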