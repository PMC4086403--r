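# Transcription between BioNLP standoff structures and BioC:
# entities and event triggers become BioC annotations, events, equivalence
# groups and coreference chains become BioC relations; a `type` infon
# disambiguates the element kinds and a `typeUri` infon carries a qualified
# type name so annotations stay semantically self-describing. Coreference
# links sharing a subject merge into a single relation.

#' Build a type URI
#'
#' Type URIs are formed as `uima:ts:` + qualified type name. The `uima:`
#' scheme hints at the origin of the type definitions and `ts` marks the
#' type-system aspect.
#'
#' @param qualified_name Dot-separated qualified type name, e.g.
#'   `"uima.tcas.Annotation"`.
#' @param prefix URI prefix; default `"uima:ts:"`.
#' @return The URI string.
#' @examples
#' make_type_uri("uima.tcas.Annotation")
#' @export
make_type_uri <- function(qualified_name, prefix = "uima:ts:") {
  stopifnot(is.character(qualified_name), length(qualified_name) == 1L)
  if (is.na(qualified_name) || !nzchar(qualified_name)) {
    stop("qualified type name must be non-empty", call. = FALSE)
  }
  paste0(prefix, qualified_name)
}

#' Type-URI map for the transcription scheme
#'
#' One qualified type name per annotation kind produced by the transcription
#' (Entity, Trigger, Event, Equivalent, Coreference). The defaults are
#' configurable; only the `uima:ts:` + qualified-name construction is fixed.
#'
#' @param entity,trigger,event,equivalent,coreference Qualified type names.
#' @param prefix URI scheme prefix passed to [make_type_uri()].
#' @return Named list of URIs keyed by kind, class `type_uri_map`.
#' @export
type_uri_map <- function(entity = "uk.ac.nactem.bionlpst.Entity",
                         trigger = "uk.ac.nactem.bionlpst.EventTrigger",
                         event = "uk.ac.nactem.bionlpst.Event",
                         equivalent = "uk.ac.nactem.bionlpst.EquivalentEntities",
                         coreference = "uk.ac.nactem.bionlpst.Relation",
                         prefix = "uima:ts:") {
  structure(list(Entity = make_type_uri(entity, prefix),
                 Trigger = make_type_uri(trigger, prefix),
                 Event = make_type_uri(event, prefix),
                 Equivalent = make_type_uri(equivalent, prefix),
                 Coreference = make_type_uri(coreference, prefix)),
            class = "type_uri_map")
}

.trigger_ann_id <- function(begin, end) sprintf("TRIGGER_%d_%d", begin, end)

#' Transcribe a standoff document into a BioC document
#'
#' The whole document becomes one BioC passage at offset 0. Entities keep
#' their ids and become annotations with `typeUri`/`type=Entity`/`category`
#' infons and one location. Event triggers become annotations with id
#' `TRIGGER_<begin>_<end>` (events sharing a trigger span reuse one
#' annotation) and `type=Trigger`. Events become relations keeping their ids,
#' with `negation`/`speculation` infons reflecting any Modification, a first
#' node referencing the trigger with role `EventTrigger`, then one node per
#' argument in source order; arguments referencing other events use the
#' target relation id. Equivalence groups become `type=Equivalent` relations
#' with empty-role nodes and ids `EE1`, `EE2`, ... in document order.
#' Coreference links sharing a subject merge into one `type=Coreference`
#' relation with id `R` + subject id, a `Subject` node and `Object` nodes in
#' source order.
#'
#' @param doc A valid [standoff_document()].
#' @param uris A [type_uri_map()].
#' @return A [bioc_document()].
#' @export
bionlp_to_bioc <- function(doc, uris = type_uri_map()) {
  viol <- validate_standoff(doc)
  if (length(viol)) {
    stop(sprintf("reference error: %s", paste(viol, collapse = "; ")),
         call. = FALSE)
  }
  tids <- names(doc$text_bounds)
  trig_ids <- unique(vapply(doc$events, `[[`, "", "trigger"))
  arg_ids <- unique(unlist(lapply(doc$events, function(e) e$args$target)))
  other_refs <- unique(c(arg_ids,
                         unlist(lapply(doc$equivalences, `[[`, "members")),
                         vapply(doc$coreferences, `[[`, "", "subject"),
                         vapply(doc$coreferences, `[[`, "", "object")))
  entity_ids <- tids[!(tids %in% trig_ids) | tids %in% other_refs]

  anns <- list()
  for (id in entity_ids[order(.numeric_id(entity_ids))]) {
    tb <- doc$text_bounds[[id]]
    anns[[length(anns) + 1L]] <- bioc_annotation(
      id = tb$id,
      infons = c(typeUri = uris$Entity, type = "Entity", category = tb$category),
      locations = list(bioc_location(tb$begin, tb$end - tb$begin)),
      text = tb$text)
  }
  # one trigger annotation per distinct span, in event id order
  seen_spans <- character()
  for (ev in doc$events[order(.numeric_id(names(doc$events)))]) {
    tb <- doc$text_bounds[[ev$trigger]]
    key <- .trigger_ann_id(tb$begin, tb$end)
    if (key %in% seen_spans) next
    seen_spans <- c(seen_spans, key)
    anns[[length(anns) + 1L]] <- bioc_annotation(
      id = key,
      infons = c(typeUri = uris$Trigger, type = "Trigger"),
      locations = list(bioc_location(tb$begin, tb$end - tb$begin)),
      text = tb$text)
  }

  rels <- list()
  mod_by_event <- list()
  for (m in doc$modifications) {
    mod_by_event[[m$target]] <- c(mod_by_event[[m$target]], m$kind)
  }
  for (ev in doc$events[order(.numeric_id(names(doc$events)))]) {
    tb <- doc$text_bounds[[ev$trigger]]
    kinds <- mod_by_event[[ev$id]]
    nodes <- list(bioc_node(.trigger_ann_id(tb$begin, tb$end), "EventTrigger"))
    if (nrow(ev$args)) {
      for (k in seq_len(nrow(ev$args))) {
        nodes[[length(nodes) + 1L]] <- bioc_node(ev$args$target[k], ev$args$role[k])
      }
    }
    rels[[length(rels) + 1L]] <- bioc_relation(
      id = ev$id,
      infons = c(typeUri = uris$Event, type = "Event", category = ev$category,
                 negation = tolower(as.character("Negation" %in% kinds)),
                 speculation = tolower(as.character("Speculation" %in% kinds))),
      nodes = nodes)
  }
  for (gi in seq_along(doc$equivalences)) {
    g <- doc$equivalences[[gi]]
    members <- g$members[order(.numeric_id(g$members))]
    rels[[length(rels) + 1L]] <- bioc_relation(
      id = sprintf("EE%d", gi),
      infons = c(typeUri = uris$Equivalent, type = "Equivalent"),
      nodes = lapply(members, bioc_node, role = ""))
  }
  if (length(doc$coreferences)) {
    subjects <- vapply(doc$coreferences, `[[`, "", "subject")
    for (subj in unique(subjects)) {
      links <- doc$coreferences[subjects == subj]
      nodes <- c(list(bioc_node(subj, "Subject")),
                 unname(lapply(links, function(l) bioc_node(l$object, "Object"))))
      rels[[length(rels) + 1L]] <- bioc_relation(
        id = paste0("R", subj),
        infons = c(typeUri = uris$Coreference, type = "Coreference"),
        nodes = nodes)
    }
  }
  bioc_document(id = doc$doc_id,
                passages = list(bioc_passage(offset = 0L, text = doc$text,
                                             annotations = anns,
                                             relations = rels)))
}

#' Transcribe a BioC document back to standoff
#'
#' Inverse of [bionlp_to_bioc()] up to id renaming of triggers and
#' coreference links: trigger annotations are re-issued `T` ids continuing
#' after the highest entity id, with their category recovered from the
#' referencing Event relation; a trigger referenced by events of conflicting
#' categories yields one `T` line per distinct span-category pair (with a
#' warning). Each `Object` node of a merged Coreference relation is
#' re-expanded into its own link with a regenerated `R` id.
#'
#' @param doc A [bioc_document()] whose annotations/relations carry the
#'   `type` infons of the transcription scheme.
#' @return A [standoff_document()].
#' @export
bioc_to_bionlp <- function(doc) {
  text <- bioc_document_text(doc)
  anns <- .doc_annotations(doc)
  rels <- .doc_relations(doc)
  ann_type <- vapply(anns, function(a) {
    t <- a$infons[["type"]]; if (is.null(t)) "" else t
  }, character(1))
  rel_type <- vapply(rels, function(r) {
    t <- r$infons[["type"]]; if (is.null(t)) "" else t
  }, character(1))

  tbs <- list()
  for (a in anns[ann_type == "Entity"]) {
    loc <- a$locations[[1]]
    tbs[[length(tbs) + 1L]] <- text_bound(
      a$id, a$infons[["category"]], loc$offset, loc$offset + loc$length, a$text)
  }
  trig_anns <- anns[ann_type == "Trigger"]
  names(trig_anns) <- vapply(trig_anns, `[[`, "", "id")

  next_t <- if (length(tbs)) {
    max(.numeric_id(vapply(tbs, `[[`, "", "id"))) + 1L
  } else 1L
  trig_tid <- new.env(parent = emptyenv())  # (annid|category) -> T id
  evs <- list(); mods <- list(); n_mod <- 0L
  ev_rels <- rels[rel_type == "Event"]
  ev_rels <- ev_rels[order(.numeric_id(vapply(ev_rels, `[[`, "", "id")))]
  for (r in ev_rels) {
    roles <- vapply(r$nodes, `[[`, "", "role")
    if (!length(roles) || roles[1] != "EventTrigger") {
      stop(sprintf("structural error: Event relation %s has no EventTrigger node",
                   r$id), call. = FALSE)
    }
    category <- r$infons[["category"]]
    trig_ref <- r$nodes[[1]]$refid
    ta <- trig_anns[[trig_ref]]
    if (is.null(ta)) {
      stop(sprintf("structural error: Event %s references missing trigger %s",
                   r$id, trig_ref), call. = FALSE)
    }
    key <- paste(trig_ref, category, sep = "|")
    tid <- trig_tid[[key]]
    if (is.null(tid)) {
      existing <- ls(trig_tid)
      if (any(startsWith(existing, paste0(trig_ref, "|")))) {
        warning(sprintf("trigger %s referenced by events of conflicting categories",
                        trig_ref))
      }
      tid <- sprintf("T%d", next_t); next_t <- next_t + 1L
      assign(key, tid, envir = trig_tid)
      loc <- ta$locations[[1]]
      tbs[[length(tbs) + 1L]] <- text_bound(
        tid, category, loc$offset, loc$offset + loc$length, ta$text)
    }
    args <- data.frame(role = character(), target = character(),
                       stringsAsFactors = FALSE)
    if (length(r$nodes) > 1L) {
      args <- data.frame(
        role = vapply(r$nodes[-1], `[[`, "", "role"),
        target = vapply(r$nodes[-1], `[[`, "", "refid"),
        stringsAsFactors = FALSE)
    }
    evs[[length(evs) + 1L]] <- standoff_event(r$id, category, tid, args)
    for (kind in c("Negation", "Speculation")) {
      flag <- r$infons[[tolower(kind)]]
      if (identical(flag, "true")) {
        n_mod <- n_mod + 1L
        mods[[length(mods) + 1L]] <- standoff_modification(
          sprintf("M%d", n_mod), kind, r$id)
      }
    }
  }
  eqs <- lapply(rels[rel_type == "Equivalent"], function(r) {
    equiv_group(vapply(r$nodes, `[[`, "", "refid"))
  })
  crs <- list(); n_r <- 0L
  for (r in rels[rel_type == "Coreference"]) {
    roles <- vapply(r$nodes, `[[`, "", "role")
    subj <- r$nodes[[which(roles == "Subject")[1]]]$refid
    for (nd in r$nodes[roles == "Object"]) {
      n_r <- n_r + 1L
      crs[[length(crs) + 1L]] <- coref_link(sprintf("R%d", n_r), subj, nd$refid)
    }
  }
  standoff_document(doc$id, text, tbs, evs, mods, eqs, crs)
}

#' Transcribe a list of standoff documents into a BioC collection
#'
#' @param docs A [standoff_document()] or list of them.
#' @param uris A [type_uri_map()].
#' @param source Collection `source` field.
#' @return A [bioc_collection()].
#' @export
bionlp_to_bioc_collection <- function(docs, uris = type_uri_map(),
                                      source = "bioconc") {
  if (inherits(docs, "standoff_document")) docs <- list(docs)
  bioc_collection(source = source, date = "", key = "",
                  documents = lapply(docs, bionlp_to_bioc, uris = uris))
}

#' Transcribe a BioC collection back to standoff documents
#'
#' @param collection A [bioc_collection()] produced by the transcription
#'   scheme.
#' @return Named list of [standoff_document()] objects.
#' @export
bioc_to_bionlp_collection <- function(collection) {
  docs <- lapply(collection$documents, bioc_to_bionlp)
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  docs
}
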