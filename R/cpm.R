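# Common Provenance Model backbone construction.
#
# The provenance backbone is a chain of main activities, each documenting
# its inputs as backward connectors and outputs as forward connectors:
#   observation unit   <- sample, vessel, protocol, feed materials,
#                         chemical compounds     -> data for analysis, logfiles
#   sample processing  <- sample                 -> processed sample(s)
#   sample collection  <- source                 -> sample
# Activities that share an entity (a sample produced by one and consumed by
# another) are chained with directed edges.

CPM_ROLES <- list(
  observation_unit = list(
    backward = c("sample", "vessel", "protocol", "feed_materials", "chemical_compounds"),
    forward = c("data_for_analysis", "logfiles")),
  sample_processing = list(backward = "sample", forward = "processed_sample"),
  sample_collection = list(backward = "source", forward = "sample")
)

# default substring matching of term names to connector roles
DEFAULT_ROLE_MAP <- list(
  vessel = "vessel",
  protocol = "protocol",
  feed_materials = "feed",
  chemical_compounds = "compound",
  data_for_analysis = "data",
  logfiles = c("logfile", "log file"),
  source = "source"
)

empty_connectors <- function() {
  tibble::tibble(activity = character(0), direction = character(0),
                 role = character(0), entity = character(0))
}

#' Build a CPM provenance backbone from a validated dataset
#'
#' One observation-unit activity per observation-unit record, one
#' sample-collection activity per sample record (sample-processing instead
#' when a sample's parent is itself a sample), with connector roles drawn
#' from the fixed role sets above. Role-to-term matching is substring-based
#' on term names and overridable.
#'
#' @param schema the governing `mim_schema`
#' @param dataset a `metadata_dataset` with zero validation errors
#' @param role_map named list role -> character vector of term-name
#'   substrings; merged over the defaults
#' @return a `cpm_backbone`: activities, connectors and chain edges
#' @export
build_cpm_backbone <- function(schema, dataset, role_map = NULL) {
  report <- validate_dataset(schema, dataset)
  if (!report$pass) {
    stop_fermeta(sprintf("dataset has %d validation error(s); backbone refused",
                         report$counts[["error"]]), "fermeta_cpm_error")
  }
  rm_map <- DEFAULT_ROLE_MAP
  for (nm in names(role_map)) rm_map[[nm]] <- role_map[[nm]]

  recs <- dataset$records
  obs <- recs[norm_token(recs$level) == "observation unit", , drop = FALSE]
  samp <- recs[norm_token(recs$level) == "sample", , drop = FALSE]
  sample_ids <- samp$identifier

  activities <- tibble::tibble(id = character(0), kind = character(0),
                               level = character(0), identifier = character(0))
  connectors <- empty_connectors()
  add_act <- function(kind, level, id) {
    aid <- paste0(gsub("_", "-", kind), "/", id)
    activities <<- rbind(activities, tibble::tibble(
      id = aid, kind = kind, level = level, identifier = id))
    aid
  }
  add_conn <- function(aid, direction, role, entity) {
    connectors <<- rbind(connectors, tibble::tibble(
      activity = aid, direction = direction, role = role, entity = entity))
  }
  match_terms <- function(level, role) {
    tm <- terms_at(schema, level)
    pats <- rm_map[[role]]
    if (is.null(pats)) return(tm[0, , drop = FALSE])
    hit <- Reduce(`|`, lapply(pats, function(p) grepl(p, norm_token(tm$name), fixed = TRUE)))
    tm[hit, , drop = FALSE]
  }
  populated_tokens <- function(rec_values, tm) {
    toks <- character(0)
    for (nm in tm$name) {
      hit <- which(norm_token(names(rec_values)) == norm_token(nm))
      if (length(hit) > 0) toks <- c(toks, unlist(rec_values[hit], use.names = FALSE))
    }
    toks
  }

  for (r in seq_len(nrow(obs))) {
    aid <- add_act("observation_unit", obs$level[r], obs$identifier[r])
    for (role in CPM_ROLES$observation_unit$backward) {
      if (role == "sample") {
        children <- samp$identifier[!is.na(samp$parent_identifier) &
                                      samp$parent_identifier == obs$identifier[r]]
        for (s in children) add_conn(aid, "backward", "sample", s)
      } else {
        for (tok in populated_tokens(obs$values[[r]], match_terms(obs$level[r], role))) {
          add_conn(aid, "backward", role, tok)
        }
      }
    }
    for (role in CPM_ROLES$observation_unit$forward) {
      for (tok in populated_tokens(obs$values[[r]], match_terms(obs$level[r], role))) {
        add_conn(aid, "forward", role, tok)
      }
    }
  }
  for (r in seq_len(nrow(samp))) {
    pid <- samp$parent_identifier[r]
    if (!is.na(pid) && pid %in% sample_ids) {
      # sample processed from another sample
      aid <- add_act("sample_processing", samp$level[r], samp$identifier[r])
      add_conn(aid, "backward", "sample", pid)
      add_conn(aid, "forward", "processed_sample", samp$identifier[r])
    } else {
      aid <- add_act("sample_collection", samp$level[r], samp$identifier[r])
      for (tok in populated_tokens(samp$values[[r]], match_terms(samp$level[r], "source"))) {
        add_conn(aid, "backward", "source", tok)
      }
      add_conn(aid, "forward", "sample", samp$identifier[r])
    }
  }

  # chain edges: producer (forward connector) -> consumer (backward connector)
  fwd <- connectors[connectors$direction == "forward", , drop = FALSE]
  bwd <- connectors[connectors$direction == "backward", , drop = FALSE]
  edges <- tibble::tibble(from = character(0), to = character(0), entity = character(0))
  for (i in seq_len(nrow(fwd))) {
    hits <- bwd[bwd$entity == fwd$entity[i] & bwd$activity != fwd$activity[i], , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      edges <- rbind(edges, tibble::tibble(from = fwd$activity[i],
                                           to = hits$activity[j],
                                           entity = fwd$entity[i]))
    }
  }
  backbone <- structure(list(activities = activities, connectors = connectors,
                             edges = edges),
                        class = "cpm_backbone")
  assert_acyclic(backbone)
  backbone
}

assert_acyclic <- function(backbone) {
  edges <- backbone$edges
  nodes <- backbone$activities$id
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (t in edges$to) indeg[[t]] <- indeg[[t]] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    n <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- edges[edges$from == n, , drop = FALSE]
    for (t in out$to) {
      indeg[[t]] <- indeg[[t]] - 1L
      if (indeg[[t]] == 0L) queue <- c(queue, t)
    }
  }
  if (seen != length(nodes)) {
    stop_fermeta("provenance backbone contains a cycle", "fermeta_cpm_error")
  }
  invisible(backbone)
}

#' @export
print.cpm_backbone <- function(x, ...) {
  cat(sprintf("<cpm_backbone> %d activity(ies) [%s], %d connector(s), %d chain edge(s)\n",
              nrow(x$activities),
              paste(sprintf("%s: %d", names(table(x$activities$kind)),
                            as.integer(table(x$activities$kind))), collapse = ", "),
              nrow(x$connectors), nrow(x$edges)))
  invisible(x)
}

#' Serialise a CPM backbone as a PROV-style RDF graph
#'
#' Each main activity becomes a PROV activity node; backward connectors are
#' usage edges (prov:used), forward connectors generation edges
#' (prov:generated). Exactly 1 + backward + forward triples per activity;
#' output is deterministic.
#'
#' @param backbone a `cpm_backbone`
#' @param path output Turtle path; NULL to return the triple set only
#' @param base_iri base IRI for activity and entity nodes
#' @return a `triple_set`, invisibly when written
#' @export
serialize_backbone <- function(backbone, path = NULL,
                               base_iri = "https://example.org/fermeta/prov/") {
  stopifnot(inherits(backbone, "cpm_backbone"))
  prov <- "http://www.w3.org/ns/prov#"
  enc <- function(x) utils::URLencode(x, reserved = TRUE)
  act_iri <- function(id) paste0(base_iri, "activity/", enc(id))
  ent_iri <- function(e) paste0(base_iri, "entity/", enc(e))
  rows <- list()
  push <- function(s, p, o) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      subject = s, predicate = p, object = o,
      object_type = "iri", datatype = NA_character_)
  }
  for (i in seq_len(nrow(backbone$activities))) {
    push(act_iri(backbone$activities$id[i]), RDF_TYPE, paste0(prov, "Activity"))
  }
  cn <- backbone$connectors
  for (i in seq_len(nrow(cn))) {
    pred <- if (cn$direction[i] == "backward") paste0(prov, "used") else paste0(prov, "generated")
    push(act_iri(cn$activity[i]), pred, ent_iri(cn$entity[i]))
  }
  triples <- if (length(rows) == 0) empty_triples() else do.call(rbind, rows)
  triples <- triples[order(triples$subject, triples$predicate, triples$object,
                           method = "radix"), , drop = FALSE]
  ts <- structure(list(triples = triples,
                       prefix_map = c(prov = prov),
                       config = rdf_export_config(base_iri)),
                  class = "triple_set")
  if (!is.null(path)) {
    write_rdf(ts, path, serialization = "turtle")
    return(invisible(ts))
  }
  ts
}
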