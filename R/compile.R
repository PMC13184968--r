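# Compile a minimum-information schema into a LinkML-dialect schema
# document: one class per metadata level, one slot per term plus an
# identifier slot per class and a parent-reference slot per non-root class.
# Term slots are required iff the term is mandatory; recommended strictness
# becomes a "recommended" annotation, not an obligation.

SYNTAX_RANGES <- c(string = "string", text = "string", integer = "integer",
                   decimal = "float", boolean = "boolean", date = "date",
                   datetime = "datetime", url = "string", email = "string",
                   orcid = "string", curie = "string")

SYNTAX_PATTERNS <- c(
  url = "^[A-Za-z][A-Za-z0-9+.\\-]*://\\S+$",
  email = "^[^@\\s]+@[^@\\s]+$",
  orcid = "^\\d{4}-\\d{4}-\\d{4}-\\d{3}[\\dX]$",
  curie = "^[A-Za-z_][\\w.\\-]*:\\S+$"
)

empty_slots <- function() {
  tibble::tibble(name = character(0), owner = character(0), kind = character(0),
                 range = character(0), required = logical(0),
                 recommended = logical(0), multivalued = logical(0),
                 unit = character(0), predicate = character(0),
                 pattern = character(0), mapped_object = character(0),
                 description = character(0))
}

#' Compile a schema into a LinkML-dialect schema document
#'
#' Deterministic: the same schema always compiles to an identical document.
#' Slot name collisions across levels are tolerated; slots are class-scoped
#' (owner column) so the printed term names are preserved.
#'
#' @param schema a valid `mim_schema`
#' @return a `schema_document`: list with `name`, `classes` tibble,
#'   `slots` tibble, `enums` list and `prefix_map`
#' @export
compile_schema <- function(schema) {
  validate_mim_schema(schema)
  lv <- schema$levels
  classes <- tibble::tibble(
    name = lv$name,
    description = lv$description,
    parent_reference_slot = ifelse(is.na(lv$parent_level), NA_character_,
                                   paste0(slugify(lv$name), "_parent")),
    class_uri = lv$mapped_object,
    extends = lv$extends
  )
  slots <- empty_slots()
  enums <- list()
  for (k in seq_len(nrow(lv))) {
    lname <- lv$name[k]
    slots <- rbind(slots, tibble::tibble(
      name = paste0(slugify(lname), "_identifier"), owner = lname,
      kind = "identifier", range = "string", required = TRUE,
      recommended = FALSE, multivalued = FALSE, unit = NA_character_,
      predicate = NA_character_, pattern = NA_character_,
      mapped_object = NA_character_,
      description = sprintf("Unique identifier of a %s record.", lname)))
    if (!is.na(lv$parent_level[k])) {
      slots <- rbind(slots, tibble::tibble(
        name = paste0(slugify(lname), "_parent"), owner = lname,
        kind = "parent", range = lv$parent_level[k], required = TRUE,
        recommended = FALSE, multivalued = FALSE, unit = NA_character_,
        predicate = NA_character_, pattern = NA_character_,
        mapped_object = NA_character_,
        description = sprintf("Reference to the parent %s record.",
                              lv$parent_level[k])))
    }
    tm <- terms_at(schema, lname)
    for (i in seq_len(nrow(tm))) {
      syn_kind <- tm$syntax[i]
      if (syn_kind == "controlled") {
        ename <- paste0(slugify(tm$name[i]), "_enum")
        enums[[ename]] <- tm$allowed_values[[i]]
        slot_range <- ename
      } else {
        slot_range <- SYNTAX_RANGES[[syn_kind]]
      }
      slots <- rbind(slots, tibble::tibble(
        name = tm$name[i], owner = lname, kind = "term", range = slot_range,
        required = tm$strictness[i] == "mandatory",
        recommended = tm$strictness[i] == "recommended",
        multivalued = tm$multivalued[i],
        unit = tm$preferred_unit[i],
        predicate = tm$predicate[i],
        pattern = if (syn_kind %in% names(SYNTAX_PATTERNS))
          SYNTAX_PATTERNS[[syn_kind]] else NA_character_,
        mapped_object = tm$mapped_object[i],
        description = tm$definition[i]))
    }
  }
  structure(list(name = schema$name, classes = classes, slots = slots,
                 enums = enums, prefix_map = schema$prefix_map),
            class = "schema_document")
}

#' @export
print.schema_document <- function(x, ...) {
  cat(sprintf("<schema_document> %s: %d class(es), %d slot(s) (%d term, %d required), %d enum(s)\n",
              x$name, nrow(x$classes), nrow(x$slots),
              sum(x$slots$kind == "term"), sum(x$slots$required & x$slots$kind == "term"),
              length(x$enums)))
  invisible(x)
}

doc_to_list <- function(doc) {
  out <- list(
    id = paste0("https://w3id.org/fermeta/", slugify(doc$name)),
    name = slugify(doc$name),
    description = sprintf("Minimum-information schema document compiled from the '%s' spreadsheet model.", doc$name),
    default_range = "string"
  )
  if (length(doc$prefix_map) > 0) {
    out$prefixes <- as.list(doc$prefix_map)
  }
  if (length(doc$enums) > 0) {
    out$enums <- lapply(doc$enums, function(vals) {
      list(permissible_values = stats::setNames(
        lapply(vals, function(v) list(text = v)), vals))
    })
  }
  classes <- list()
  for (k in seq_len(nrow(doc$classes))) {
    cl <- doc$classes[k, ]
    sl <- doc$slots[doc$slots$owner == cl$name, , drop = FALSE]
    attrs <- list()
    for (i in seq_len(nrow(sl))) {
      a <- list(range = sl$range[i])
      if (sl$required[i]) a$required <- TRUE
      if (sl$recommended[i]) a$recommended <- TRUE
      if (sl$multivalued[i]) a$multivalued <- TRUE
      if (!is.na(sl$pattern[i])) a$pattern <- sl$pattern[i]
      if (!is.na(sl$predicate[i])) a$slot_uri <- sl$predicate[i]
      if (!is.na(sl$mapped_object[i])) a$exact_mappings <- list(sl$mapped_object[i])
      if (!is.na(sl$unit[i])) {
        a$annotations <- list(preferred_unit = sl$unit[i])
      }
      if (!is.na(sl$description[i])) a$description <- sl$description[i]
      attrs[[sl$name[i]]] <- a
    }
    cdef <- list()
    if (!is.na(cl$description)) cdef$description <- cl$description
    if (!is.na(cl$class_uri)) cdef$class_uri <- cl$class_uri
    if (!is.na(cl$extends)) cdef$exact_mappings <- list(cl$extends)
    cdef$attributes <- attrs
    classes[[cl$name]] <- cdef
  }
  if (length(classes) > 0) out$classes <- classes
  out
}

#' Emit a schema document as YAML
#'
#' Key ordering is fixed by construction; emitting the same document twice
#' produces byte-identical files.
#'
#' @param doc a `schema_document`
#' @param path output .yaml path
#' @return the path, invisibly
#' @export
emit_yaml <- function(doc, path) {
  stopifnot(inherits(doc, "schema_document"))
  txt <- yaml::as.yaml(doc_to_list(doc), indent.mapping.sequence = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "")
  invisible(path)
}
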