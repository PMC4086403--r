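# BioC XML serialization via xml2. The element vocabulary follows the BioC
# DTD: collection > source/date/key/infon*/document*, document > id/infon*/
# passage*, passage > infon*/offset/text?/sentence*/annotation*/relation*,
# sentence > infon*/offset/text?/annotation*/relation*, annotation >
# infon*/location*/text, relation > infon*/node*.

.xml_text_of <- function(node, name) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing")) "" else xml2::xml_text(child)
}

.read_infons <- function(node) {
  infon_nodes <- xml2::xml_find_all(node, "infon")
  if (!length(infon_nodes)) return(setNames(character(), character()))
  vals <- xml2::xml_text(infon_nodes)
  keys <- xml2::xml_attr(infon_nodes, "key")
  if (anyDuplicated(keys)) {
    stop(sprintf("BioC schema error at %s: duplicate infon key", xml2::xml_path(node)),
         call. = FALSE)
  }
  setNames(vals, keys)
}

.read_annotation <- function(node) {
  locs <- lapply(xml2::xml_find_all(node, "location"), function(l) {
    bioc_location(as.integer(xml2::xml_attr(l, "offset")),
                  as.integer(xml2::xml_attr(l, "length")))
  })
  bioc_annotation(id = xml2::xml_attr(node, "id"),
                  infons = .read_infons(node),
                  locations = locs,
                  text = .xml_text_of(node, "text"))
}

.read_relation <- function(node) {
  nodes <- lapply(xml2::xml_find_all(node, "node"), function(n) {
    role <- xml2::xml_attr(n, "role")
    bioc_node(xml2::xml_attr(n, "refid"), if (is.na(role)) "" else role)
  })
  bioc_relation(id = xml2::xml_attr(node, "id"),
                infons = .read_infons(node), nodes = nodes)
}

.read_sentence <- function(node) {
  text_node <- xml2::xml_find_first(node, "text")
  bioc_sentence(
    offset = as.integer(.xml_text_of(node, "offset")),
    text = if (inherits(text_node, "xml_missing")) NULL else xml2::xml_text(text_node),
    infons = .read_infons(node),
    annotations = lapply(xml2::xml_find_all(node, "annotation"), .read_annotation),
    relations = lapply(xml2::xml_find_all(node, "relation"), .read_relation))
}

.read_passage <- function(node) {
  text_node <- xml2::xml_find_first(node, "text")
  bioc_passage(
    offset = as.integer(.xml_text_of(node, "offset")),
    text = if (inherits(text_node, "xml_missing")) NULL else xml2::xml_text(text_node),
    infons = .read_infons(node),
    sentences = lapply(xml2::xml_find_all(node, "sentence"), .read_sentence),
    annotations = lapply(xml2::xml_find_all(node, "annotation"), .read_annotation),
    relations = lapply(xml2::xml_find_all(node, "relation"), .read_relation))
}

.bioc_allowed_children <- list(
  collection = c("source", "date", "key", "infon", "document"),
  document = c("id", "infon", "passage"),
  passage = c("infon", "offset", "text", "sentence", "annotation", "relation"),
  sentence = c("infon", "offset", "text", "annotation", "relation"),
  annotation = c("infon", "location", "text"),
  relation = c("infon", "node")
)

.check_bioc_elements <- function(root) {
  if (xml2::xml_name(root) != "collection") {
    stop(sprintf("BioC schema error at %s: root element must be <collection>",
                 xml2::xml_path(root)), call. = FALSE)
  }
  walk <- function(node) {
    name <- xml2::xml_name(node)
    allowed <- .bioc_allowed_children[[name]]
    if (is.null(allowed)) return(invisible())
    for (child in xml2::xml_children(node)) {
      cname <- xml2::xml_name(child)
      if (!cname %in% allowed) {
        stop(sprintf("BioC schema error at %s: element <%s> not allowed under <%s>",
                     xml2::xml_path(child), cname, name), call. = FALSE)
      }
      walk(child)
    }
  }
  walk(root)
}

#' Read a BioC XML collection
#'
#' @param x XML content: a file path, a single string, or a raw vector.
#' @param dtd Optional path to a BioC DTD; when supplied, the document is
#'   additionally validated against it.
#' @return A [bioc_collection()]. Malformed XML raises a parse error; an
#'   element outside the BioC vocabulary raises a schema error naming the
#'   element path. Unresolvable node refids are reported as a warning (use
#'   [validate_bioc()] for the full record set).
#' @examples
#' xml <- write_bioc(bioc_collection(source = "demo"))
#' read_bioc(xml)
#' @export
read_bioc <- function(x, dtd = NULL) {
  doc <- if (is.raw(x)) {
    xml2::read_xml(x)
  } else if (length(x) == 1L && !grepl("<", x, fixed = TRUE) && file.exists(x)) {
    xml2::read_xml(x)
  } else {
    xml2::read_xml(paste(x, collapse = "\n"))
  }
  if (!is.null(dtd)) {
    ok <- xml2::xml_validate(doc, xml2::read_xml(dtd))
    if (!isTRUE(ok)) {
      stop(sprintf("BioC DTD validation failed: %s",
                   paste(attr(ok, "errors"), collapse = "; ")), call. = FALSE)
    }
  }
  root <- xml2::xml_root(doc)
  .check_bioc_elements(root)
  coll <- bioc_collection(
    source = .xml_text_of(root, "source"),
    date = .xml_text_of(root, "date"),
    key = .xml_text_of(root, "key"),
    infons = .read_infons(root),
    documents = lapply(xml2::xml_find_all(root, "document"), function(d) {
      bioc_document(id = .xml_text_of(d, "id"),
                    infons = .read_infons(d),
                    passages = lapply(xml2::xml_find_all(d, "passage"),
                                      .read_passage))
    }))
  dangling <- validate_bioc(coll)
  dangling <- dangling[grepl("refid", dangling$rule), , drop = FALSE]
  if (nrow(dangling)) {
    warning(sprintf("unresolved node refid(s): %s",
                    paste(unique(dangling$path), collapse = "; ")))
  }
  coll
}

.write_infons <- function(parent, infons) {
  for (k in names(infons)) {
    node <- xml2::xml_add_child(parent, "infon", key = k)
    xml2::xml_text(node) <- infons[[k]]
  }
}

.write_annotation <- function(parent, a) {
  node <- xml2::xml_add_child(parent, "annotation", id = a$id)
  .write_infons(node, a$infons)
  for (loc in a$locations) {
    xml2::xml_add_child(node, "location",
                        offset = as.character(loc$offset),
                        length = as.character(loc$length))
  }
  tnode <- xml2::xml_add_child(node, "text")
  xml2::xml_text(tnode) <- a$text
}

.write_relation <- function(parent, r) {
  node <- xml2::xml_add_child(parent, "relation", id = r$id)
  .write_infons(node, r$infons)
  for (nd in r$nodes) {
    xml2::xml_add_child(node, "node", refid = nd$refid, role = nd$role)
  }
}

.write_sentence <- function(parent, s) {
  node <- xml2::xml_add_child(parent, "sentence")
  .write_infons(node, s$infons)
  onode <- xml2::xml_add_child(node, "offset")
  xml2::xml_text(onode) <- as.character(s$offset)
  if (!is.null(s$text)) {
    tnode <- xml2::xml_add_child(node, "text")
    xml2::xml_text(tnode) <- s$text
  }
  for (a in s$annotations) .write_annotation(node, a)
  for (r in s$relations) .write_relation(node, r)
}

.write_passage <- function(parent, p) {
  node <- xml2::xml_add_child(parent, "passage")
  .write_infons(node, p$infons)
  onode <- xml2::xml_add_child(node, "offset")
  xml2::xml_text(onode) <- as.character(p$offset)
  if (!is.null(p$text)) {
    tnode <- xml2::xml_add_child(node, "text")
    xml2::xml_text(tnode) <- p$text
  }
  for (s in p$sentences) .write_sentence(node, s)
  for (a in p$annotations) .write_annotation(node, a)
  for (r in p$relations) .write_relation(node, r)
}

#' Write a BioC collection as XML
#'
#' Infons are serialized in stored order; output is UTF-8 with straight ASCII
#' quotes. A dangling node refid raises a validation error before anything is
#' written.
#'
#' @param collection A [bioc_collection()].
#' @param path Optional file path; when `NULL` the XML is returned as a
#'   string.
#' @return The XML as a single string (invisibly when `path` is given).
#' @export
write_bioc <- function(collection, path = NULL) {
  viol <- validate_bioc(collection)
  refs <- viol[grepl("refid", viol$rule), , drop = FALSE]
  if (nrow(refs)) {
    stop(sprintf("BioC validation error: %s (%s)", refs$rule[1], refs$path[1]),
         call. = FALSE)
  }
  doc <- xml2::xml_new_root("collection")
  root <- xml2::xml_root(doc)
  for (field in c("source", "date", "key")) {
    node <- xml2::xml_add_child(root, field)
    xml2::xml_text(node) <- collection[[field]]
  }
  .write_infons(root, collection$infons)
  for (d in collection$documents) {
    dnode <- xml2::xml_add_child(root, "document")
    idnode <- xml2::xml_add_child(dnode, "id")
    xml2::xml_text(idnode) <- d$id
    .write_infons(dnode, d$infons)
    for (p in d$passages) .write_passage(dnode, p)
  }
  out <- as.character(doc)
  if (!is.null(path)) {
    .write_file(out, path)
    return(invisible(out))
  }
  out
}
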