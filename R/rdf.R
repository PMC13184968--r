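# RDF export of validated datasets.
#
# Every record gets a named subject IRI (base + level slug + "/" + id); one
# rdf:type triple to the level's mapped ontology class (or a local class
# IRI), one containment triple per parent link, and one property triple per
# populated declared-term token. Serialisation is deterministic: triples
# are sorted, output is byte-stable. No blank nodes.

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD <- "http://www.w3.org/2001/XMLSchema#"

XSD_DATATYPES <- c(integer = "integer", decimal = "decimal",
                   boolean = "boolean", date = "date",
                   datetime = "dateTime")

#' Configure an RDF export
#'
#' @param base_iri absolute base IRI ending in "/" or "#"
#' @param containment_predicate CURIE or IRI linking a parent record to its
#'   children; default is a local "hasPart" term under the base IRI
#' @param serialization "turtle" or "ntriples"
#' @return an `rdf_export_config`
#' @export
rdf_export_config <- function(base_iri = "https://example.org/fermeta/",
                              containment_predicate = NULL,
                              serialization = c("turtle", "ntriples")) {
  serialization <- match.arg(serialization)
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://", base_iri) ||
      !grepl("[/#]$", base_iri)) {
    stop_fermeta("base_iri must be absolute and end with '/' or '#'",
                 "fermeta_format_error")
  }
  structure(list(base_iri = base_iri,
                 containment_predicate = containment_predicate %||%
                   paste0(base_iri, "hasPart"),
                 serialization = serialization),
            class = "rdf_export_config")
}

#' Expand a CURIE to a full IRI
#'
#' @param prefix_map named character vector, prefix -> IRI base
#' @param token CURIE "prefix:local"
#' @return expanded IRI string
#' @export
expand_curie <- function(prefix_map, token) {
  m <- regmatches(token, regexec("^([A-Za-z_][A-Za-z0-9._-]*):(.*)$", token))[[1]]
  if (length(m) == 0) {
    stop_fermeta(sprintf("not a CURIE: '%s'", token), "fermeta_export_error")
  }
  base <- if (m[2] %in% names(prefix_map)) prefix_map[[m[2]]] else NULL
  if (is.null(base)) {
    stop_fermeta(sprintf("unknown CURIE prefix '%s' in '%s'", m[2], token),
                 "fermeta_export_error")
  }
  paste0(base, m[3])
}

#' Compact an IRI back to a CURIE where a prefix matches
#'
#' Longest-matching prefix wins; the IRI is returned unchanged when no
#' prefix applies.
#' @param prefix_map named character vector
#' @param iri full IRI
#' @return CURIE or the original IRI
#' @export
compact_iri <- function(prefix_map, iri) {
  if (length(prefix_map) == 0) return(iri)
  hits <- prefix_map[startsWith(iri, unname(prefix_map))]
  if (length(hits) == 0) return(iri)
  best <- hits[which.max(nchar(hits))]
  paste0(names(best), ":", substring(iri, nchar(best) + 1))
}

# a CURIE cell (predicate/object columns) may already be a full IRI
iri_or_curie <- function(prefix_map, token) {
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", token)) token
  else expand_curie(prefix_map, token)
}

empty_triples <- function() {
  tibble::tibble(subject = character(0), predicate = character(0),
                 object = character(0), object_type = character(0),
                 datatype = character(0))
}

#' Export a validated dataset as an RDF triple set
#'
#' Refuses datasets that do not validate cleanly. The triple count obeys a
#' closed form: per record, 1 type triple + 1 containment triple if the
#' record has a resolvable parent + 1 triple per populated declared-term
#' token.
#'
#' @param schema the governing `mim_schema`
#' @param dataset a `metadata_dataset` with zero validation errors
#' @param config an [rdf_export_config()]
#' @return a `triple_set`: tibble of sorted triples
#' @export
export_rdf <- function(schema, dataset, config = rdf_export_config()) {
  report <- validate_dataset(schema, dataset)
  if (!report$pass) {
    stop_fermeta(sprintf("dataset has %d validation error(s); export refused",
                         report$counts[["error"]]), "fermeta_export_error")
  }
  base <- config$base_iri
  pm <- schema$prefix_map
  recs <- dataset$records
  recs <- recs[norm_token(recs$level) %in% norm_token(schema$levels$name), , drop = FALSE]
  subject_iri <- function(level, id) {
    paste0(base, iri_slug(level), "/", utils::URLencode(id, reserved = TRUE))
  }
  triples <- list()
  push <- function(s, p, o, type, dt = NA_character_) {
    triples[[length(triples) + 1]] <<- tibble::tibble(
      subject = s, predicate = p, object = o, object_type = type, datatype = dt)
  }
  containment <- if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", config$containment_predicate)) {
    config$containment_predicate
  } else {
    expand_curie(pm, config$containment_predicate)
  }
  for (r in seq_len(nrow(recs))) {
    level <- recs$level[r]
    subj <- subject_iri(level, recs$identifier[r])
    lrow <- schema$levels[match(norm_token(level), norm_token(schema$levels$name)), ]
    class_iri <- if (!is.na(lrow$mapped_object)) {
      iri_or_curie(pm, lrow$mapped_object)
    } else {
      paste0(base, "schema/", iri_slug(level))
    }
    push(subj, RDF_TYPE, class_iri, "iri")
    if (!is.na(lrow$parent_level) && !is.na(recs$parent_identifier[r])) {
      push(subject_iri(lrow$parent_level, recs$parent_identifier[r]),
           containment, subj, "iri")
    }
    tm <- terms_at(schema, level)
    vals <- recs$values[[r]]
    for (i in seq_len(nrow(tm))) {
      hit <- which(norm_token(names(vals)) == norm_token(tm$name[i]))
      if (length(hit) == 0) next
      toks <- unlist(vals[hit], use.names = FALSE)
      pred <- if (!is.na(tm$predicate[i])) iri_or_curie(pm, tm$predicate[i]) else {
        paste0(base, "term/", slugify(tm$name[i]))
      }
      for (tok in toks) {
        kind <- tm$syntax[i]
        if (kind == "curie") {
          push(subj, pred, expand_curie(pm, tok), "iri")
        } else if (kind %in% names(XSD_DATATYPES)) {
          parts <- if (kind %in% c("integer", "decimal")) split_unit_token(tok) else list(value = tok, unit = NA)
          if (!is.na(parts$unit)) {
            push(subj, pred, tok, "literal")  # unit-bearing: plain "value unit"
          } else {
            push(subj, pred, parts$value, "literal",
                 paste0(XSD, XSD_DATATYPES[[kind]]))
          }
        } else {
          push(subj, pred, tok, "literal")
        }
      }
    }
  }
  out <- if (length(triples) == 0) empty_triples() else do.call(rbind, triples)
  out <- out[order(out$subject, out$predicate, out$object, out$datatype,
                   na.last = FALSE, method = "radix"), , drop = FALSE]
  structure(list(triples = out, prefix_map = pm, config = config),
            class = "triple_set")
}

#' @export
print.triple_set <- function(x, ...) {
  cat(sprintf("<triple_set> %d triple(s)\n", nrow(x$triples)))
  invisible(x)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

ntriples_lines <- function(triples) {
  vapply(seq_len(nrow(triples)), function(i) {
    o <- if (triples$object_type[i] == "iri") {
      sprintf("<%s>", triples$object[i])
    } else if (!is.na(triples$datatype[i])) {
      sprintf("\"%s\"^^<%s>", escape_literal(triples$object[i]), triples$datatype[i])
    } else {
      sprintf("\"%s\"", escape_literal(triples$object[i]))
    }
    sprintf("<%s> <%s> %s .", triples$subject[i], triples$predicate[i], o)
  }, character(1))
}

turtle_lines <- function(triples, prefix_map) {
  pm <- c(prefix_map,
          rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          xsd = XSD,
          prov = "http://www.w3.org/ns/prov#")
  pm <- pm[!duplicated(names(pm))]
  compact <- function(iri) {
    c <- compact_iri(pm, iri)
    if (identical(c, iri)) sprintf("<%s>", iri) else c
  }
  used <- logical(length(pm))
  term <- function(iri) {
    t <- compact(iri)
    if (!startsWith(t, "<")) used[match(sub(":.*$", "", t), names(pm))] <<- TRUE
    t
  }
  body <- vapply(seq_len(nrow(triples)), function(i) {
    o <- if (triples$object_type[i] == "iri") {
      term(triples$object[i])
    } else if (!is.na(triples$datatype[i])) {
      dt <- term(triples$datatype[i])
      sprintf("\"%s\"^^%s", escape_literal(triples$object[i]), dt)
    } else {
      sprintf("\"%s\"", escape_literal(triples$object[i]))
    }
    sprintf("%s %s %s .", term(triples$subject[i]), term(triples$predicate[i]), o)
  }, character(1))
  header <- sprintf("@prefix %s: <%s> .", names(pm)[used], unname(pm)[used])
  c(header, if (length(header)) "", body)
}

#' Write a triple set to disk
#'
#' @param x a `triple_set`
#' @param path output path (.ttl or .nt)
#' @param serialization overrides the config's serialization when given
#' @return the path, invisibly
#' @export
write_rdf <- function(x, path, serialization = NULL) {
  stopifnot(inherits(x, "triple_set"))
  serialization <- serialization %||% x$config$serialization
  lines <- if (serialization == "ntriples") {
    ntriples_lines(x$triples)
  } else {
    turtle_lines(x$triples, x$prefix_map)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
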