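# In-memory model of BioC collections. Infons are ordered key-value pairs
# attached to almost every element; they are stored as named character
# vectors whose order is preserved through read/write. Keys must be unique
# within one element (they may repeat across elements).

.check_infons <- function(infons) {
  if (is.null(infons)) return(setNames(character(), character()))
  stopifnot(is.character(infons))
  keys <- names(infons)
  if (length(infons) && (is.null(keys) || any(!nzchar(keys)))) {
    stop("infon keys must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate infon key within one element: %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ",")),
         call. = FALSE)
  }
  infons
}

#' Construct a BioC location
#'
#' @param offset 0-based character offset in the whole-document coordinate
#'   system (Unicode code points).
#' @param length Number of characters covered; must be positive.
#' @return An object of class `bioc_location`.
#' @export
bioc_location <- function(offset, length) {
  offset <- as.integer(offset); length <- as.integer(length)
  stopifnot(offset >= 0L, length > 0L)
  structure(list(offset = offset, length = length), class = "bioc_location")
}

#' Construct a BioC annotation
#'
#' @param id Annotation id (unique among annotations in its document).
#' @param infons Named character vector of key-value pairs.
#' @param locations List of [bioc_location()] objects.
#' @param text Covered text.
#' @return An object of class `bioc_annotation`.
#' @export
bioc_annotation <- function(id, infons = character(), locations = list(),
                            text = "") {
  structure(list(id = id, infons = .check_infons(infons),
                 locations = locations, text = text),
            class = "bioc_annotation")
}

#' Construct a BioC relation node
#'
#' @param refid Id of the referenced annotation or relation in the same
#'   document.
#' @param role Role string; may be empty.
#' @return An object of class `bioc_node`.
#' @export
bioc_node <- function(refid, role = "") {
  stopifnot(nzchar(refid))
  structure(list(refid = refid, role = role), class = "bioc_node")
}

#' Construct a BioC relation
#'
#' @param id Relation id (unique among relations in its document).
#' @param infons Named character vector.
#' @param nodes List of [bioc_node()] objects; at least one.
#' @return An object of class `bioc_relation`.
#' @export
bioc_relation <- function(id, infons = character(), nodes = list()) {
  structure(list(id = id, infons = .check_infons(infons), nodes = nodes),
            class = "bioc_relation")
}

#' Construct a BioC sentence
#'
#' @param offset 0-based document-level offset of the sentence.
#' @param text Sentence text, or `NULL` when not materialized.
#' @param infons Named character vector.
#' @param annotations,relations Lists of annotations/relations attached at
#'   sentence level.
#' @return An object of class `bioc_sentence`.
#' @export
bioc_sentence <- function(offset, text = NULL, infons = character(),
                          annotations = list(), relations = list()) {
  structure(list(offset = as.integer(offset), text = text,
                 infons = .check_infons(infons),
                 annotations = annotations, relations = relations),
            class = "bioc_sentence")
}

#' Construct a BioC passage
#'
#' @inheritParams bioc_sentence
#' @param sentences List of [bioc_sentence()] objects.
#' @return An object of class `bioc_passage`.
#' @export
bioc_passage <- function(offset, text = NULL, infons = character(),
                         sentences = list(), annotations = list(),
                         relations = list()) {
  structure(list(offset = as.integer(offset), text = text,
                 infons = .check_infons(infons), sentences = sentences,
                 annotations = annotations, relations = relations),
            class = "bioc_passage")
}

#' Construct a BioC document
#'
#' @param id Document id.
#' @param infons Named character vector.
#' @param passages List of [bioc_passage()] objects.
#' @return An object of class `bioc_document`.
#' @export
bioc_document <- function(id, infons = character(), passages = list()) {
  structure(list(id = id, infons = .check_infons(infons), passages = passages),
            class = "bioc_document")
}

#' Construct a BioC collection
#'
#' @param source Originating source string.
#' @param date Collection date string.
#' @param key Key file name string.
#' @param infons Named character vector.
#' @param documents List of [bioc_document()] objects.
#' @return An object of class `bioc_collection`.
#' @export
bioc_collection <- function(source = "", date = "", key = "",
                            infons = character(), documents = list()) {
  structure(list(source = source, date = date, key = key,
                 infons = .check_infons(infons), documents = documents),
            class = "bioc_collection")
}

#' @export
print.bioc_collection <- function(x, ...) {
  cat(sprintf("bioc_collection: source='%s', %d document(s)\n",
              x$source, length(x$documents)))
  invisible(x)
}

# flat views used by validation and transcription
.doc_annotations <- function(doc) {
  out <- list()
  for (p in doc$passages) {
    out <- c(out, p$annotations)
    for (s in p$sentences) out <- c(out, s$annotations)
  }
  out
}

.doc_relations <- function(doc) {
  out <- list()
  for (p in doc$passages) {
    out <- c(out, p$relations)
    for (s in p$sentences) out <- c(out, s$relations)
  }
  out
}

#' Full text of a BioC document
#'
#' Concatenates passage texts padded to their document-level offsets, so that
#' annotation locations index correctly into the returned string.
#'
#' @param doc A [bioc_document()].
#' @return A single string.
#' @export
bioc_document_text <- function(doc) {
  if (!length(doc$passages)) return("")
  end <- 0L
  parts <- character()
  for (p in doc$passages) {
    ptext <- if (!is.null(p$text)) {
      p$text
    } else if (length(p$sentences)) {
      st <- ""
      send <- p$offset
      for (s in p$sentences) {
        if (!is.null(s$text)) {
          st <- paste0(st, strrep(" ", s$offset - send), s$text)
          send <- s$offset + nchar(s$text)
        }
      }
      st
    } else ""
    parts <- c(parts, strrep(" ", max(0L, p$offset - end)), ptext)
    end <- p$offset + nchar(ptext)
  }
  paste(parts, collapse = "")
}

#' Validate a BioC collection
#'
#' Violations are returned as data, not raised: each record names the element
#' path and the rule broken. Checked rules: non-empty and unique infon keys
#' per element, location sanity (`offset >= 0`, `length > 0`), per-document
#' uniqueness of annotation and relation ids, relations having at least one
#' node, node `refid`s resolving to an annotation or relation of the same
#' document, and (when text is present) agreement between an annotation's
#' `text` and the concatenation of its located substrings.
#'
#' @param collection A [bioc_collection()].
#' @return A data frame with columns `path` and `rule`; zero rows when valid.
#' @export
validate_bioc <- function(collection) {
  out <- list()
  add <- function(path, rule) out[[length(out) + 1L]] <<- list(path = path, rule = rule)
  chk_infons <- function(infons, path) {
    keys <- names(infons)
    if (length(infons) && (is.null(keys) || any(!nzchar(keys))))
      add(path, "infon key empty")
    if (anyDuplicated(keys)) add(path, "duplicate infon key")
  }
  chk_infons(collection$infons, "collection")
  for (di in seq_along(collection$documents)) {
    doc <- collection$documents[[di]]
    dpath <- sprintf("document[%s]", doc$id)
    chk_infons(doc$infons, dpath)
    anns <- .doc_annotations(doc)
    rels <- .doc_relations(doc)
    ann_ids <- vapply(anns, `[[`, "", "id")
    rel_ids <- vapply(rels, `[[`, "", "id")
    if (anyDuplicated(ann_ids)) add(dpath, "duplicate annotation id")
    if (anyDuplicated(rel_ids)) add(dpath, "duplicate relation id")
    dtext <- bioc_document_text(doc)
    for (a in anns) {
      apath <- sprintf("%s/annotation[%s]", dpath, a$id)
      chk_infons(a$infons, apath)
      for (loc in a$locations) {
        if (loc$offset < 0L) add(apath, "location offset < 0")
        if (loc$length <= 0L) add(apath, "location length <= 0")
      }
      if (nzchar(dtext) && length(a$locations)) {
        located <- paste(vapply(a$locations, function(loc) {
          if (loc$offset + loc$length <= nchar(dtext)) {
            substr0(dtext, loc$offset, loc$offset + loc$length)
          } else ""
        }, character(1)), collapse = "")
        if (nzchar(a$text) && located != a$text) {
          add(apath, "text does not match located substring")
        }
      }
    }
    known <- c(ann_ids, rel_ids)
    for (r in rels) {
      rpath <- sprintf("%s/relation[%s]", dpath, r$id)
      chk_infons(r$infons, rpath)
      if (!length(r$nodes)) add(rpath, "relation has no nodes")
      for (nd in r$nodes) {
        if (!nd$refid %in% known) {
          add(rpath, sprintf("node refid %s does not resolve", nd$refid))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(path = character(), rule = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(path = vapply(out, `[[`, "", "path"),
             rule = vapply(out, `[[`, "", "rule"),
             stringsAsFactors = FALSE)
}
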