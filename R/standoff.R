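# BioNLP shared-task standoff format: document text in a .txt file,
# annotations as plain-text T/E/M/R/Equiv lines in companion .a1/.a2 files.
# Offsets are 0-based, end-exclusive character offsets into the text.

#' Construct a text-bound annotation
#'
#' @param id Annotation identifier, pattern `T<int>`.
#' @param category Label string, e.g. `"Protein"` or `"Gene_expression"`.
#' @param begin,end 0-based character offsets, end-exclusive.
#' @param text Covered string (must have length `end - begin`).
#' @return An object of class `text_bound`.
#' @export
text_bound <- function(id, category, begin, end, text) {
  begin <- as.integer(begin); end <- as.integer(end)
  stopifnot(grepl("^T[0-9]+$", id), nzchar(category),
            begin >= 0L, end > begin, nchar(text) == end - begin)
  structure(list(id = id, category = category, begin = begin, end = end,
                 text = text),
            class = "text_bound")
}

#' Construct an event annotation
#'
#' @param id Identifier, pattern `E<int>`.
#' @param category Event label, e.g. `"Gene_expression"`.
#' @param trigger Id of the trigger [text_bound()].
#' @param args Data frame with columns `role` and `target` (T or E ids), in
#'   source order; may have zero rows.
#' @return An object of class `standoff_event`.
#' @export
standoff_event <- function(id, category, trigger, args = NULL) {
  if (is.null(args)) {
    args <- data.frame(role = character(), target = character(),
                       stringsAsFactors = FALSE)
  }
  stopifnot(grepl("^E[0-9]+$", id), nzchar(category), grepl("^T[0-9]+$", trigger),
            is.data.frame(args), all(c("role", "target") %in% names(args)))
  structure(list(id = id, category = category, trigger = trigger,
                 args = args[, c("role", "target"), drop = FALSE]),
            class = "standoff_event")
}

#' Construct an event modification (Negation or Speculation)
#'
#' @param id Identifier, pattern `M<int>`.
#' @param kind `"Negation"` or `"Speculation"`.
#' @param target Id of the modified event.
#' @return An object of class `standoff_modification`.
#' @export
standoff_modification <- function(id, kind, target) {
  stopifnot(grepl("^M[0-9]+$", id),
            kind %in% c("Negation", "Speculation"),
            grepl("^E[0-9]+$", target))
  structure(list(id = id, kind = kind, target = target),
            class = "standoff_modification")
}

#' Construct an equivalence group
#'
#' @param members Character vector of at least two distinct text-bound ids.
#' @return An object of class `equiv_group`.
#' @export
equiv_group <- function(members) {
  members <- unique(as.character(members))
  stopifnot(length(members) >= 2L, all(grepl("^T[0-9]+$", members)))
  structure(list(members = members), class = "equiv_group")
}

#' Construct a coreference link
#'
#' @param id Identifier, pattern `R<int>`.
#' @param subject,object Distinct text-bound ids.
#' @return An object of class `coref_link`.
#' @export
coref_link <- function(id, subject, object) {
  stopifnot(grepl("^R[0-9]+$", id), grepl("^T[0-9]+$", subject),
            grepl("^T[0-9]+$", object), subject != object)
  structure(list(id = id, subject = subject, object = object),
            class = "coref_link")
}

#' Construct a standoff document
#'
#' @param doc_id Document identifier.
#' @param text Full document text.
#' @param text_bounds,events,modifications,equivalences,coreferences Lists of
#'   the corresponding annotation objects.
#' @return An object of class `standoff_document`.
#' @export
standoff_document <- function(doc_id, text, text_bounds = list(),
                              events = list(), modifications = list(),
                              equivalences = list(), coreferences = list()) {
  doc <- structure(list(doc_id = doc_id, text = text,
                        text_bounds = text_bounds, events = events,
                        modifications = modifications,
                        equivalences = equivalences,
                        coreferences = coreferences),
                   class = "standoff_document")
  names(doc$text_bounds) <- vapply(text_bounds, `[[`, "", "id")
  names(doc$events) <- vapply(events, `[[`, "", "id")
  names(doc$modifications) <- vapply(modifications, `[[`, "", "id")
  names(doc$coreferences) <- vapply(coreferences, `[[`, "", "id")
  doc
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf(paste0("standoff_document '%s': %d chars, %d text-bounds, ",
                     "%d events, %d modifications, %d equiv groups, %d corefs\n"),
              x$doc_id, nchar(x$text), length(x$text_bounds), length(x$events),
              length(x$modifications), length(x$equivalences),
              length(x$coreferences)))
  invisible(x)
}

.numeric_id <- function(ids) as.integer(sub("^[A-Z]+", "", ids))

#' Validate a standoff document
#'
#' Checks id uniqueness per id class, reference resolution (event triggers,
#' event arguments, modification targets, equivalence members, coreference
#' endpoints), text/offset consistency of every text-bound against the
#' document text, absence of self-reference cycles among events, and that no
#' two equivalence groups share a member.
#'
#' @param doc A [standoff_document()].
#' @return A character vector of violation messages; empty when valid.
#' @export
validate_standoff <- function(doc) {
  v <- character()
  tids <- names(doc$text_bounds)
  eids <- names(doc$events)
  if (anyDuplicated(tids)) v <- c(v, "duplicate text-bound ids")
  if (anyDuplicated(eids)) v <- c(v, "duplicate event ids")
  if (anyDuplicated(names(doc$modifications))) v <- c(v, "duplicate modification ids")
  if (anyDuplicated(names(doc$coreferences))) v <- c(v, "duplicate coreference ids")
  for (tb in doc$text_bounds) {
    if (tb$end > nchar(doc$text)) {
      v <- c(v, sprintf("%s: span [%d,%d) exceeds text length %d",
                        tb$id, tb$begin, tb$end, nchar(doc$text)))
    } else if (substr0(doc$text, tb$begin, tb$end) != tb$text) {
      v <- c(v, sprintf("%s: covered text mismatch", tb$id))
    }
  }
  for (ev in doc$events) {
    if (!ev$trigger %in% tids)
      v <- c(v, sprintf("%s: unresolved trigger %s", ev$id, ev$trigger))
    for (tg in ev$args$target) {
      if (!(tg %in% tids || tg %in% eids))
        v <- c(v, sprintf("%s: unresolved argument target %s", ev$id, tg))
    }
  }
  for (m in doc$modifications) {
    if (!m$target %in% eids)
      v <- c(v, sprintf("%s: unresolved event target %s", m$id, m$target))
  }
  seen <- character()
  for (g in doc$equivalences) {
    bad <- setdiff(g$members, tids)
    if (length(bad))
      v <- c(v, sprintf("equivalence group: unresolved member(s) %s",
                        paste(bad, collapse = ",")))
    shared <- intersect(g$members, seen)
    if (length(shared))
      v <- c(v, sprintf("equivalence groups share member(s) %s",
                        paste(shared, collapse = ",")))
    seen <- c(seen, g$members)
  }
  for (r in doc$coreferences) {
    if (!r$subject %in% tids)
      v <- c(v, sprintf("%s: unresolved subject %s", r$id, r$subject))
    if (!r$object %in% tids)
      v <- c(v, sprintf("%s: unresolved object %s", r$id, r$object))
  }
  # event reference cycles (events may nest, but never reach themselves)
  if (length(doc$events)) {
    adj <- lapply(doc$events, function(ev) intersect(ev$args$target, eids))
    state <- setNames(rep.int(0L, length(eids)), eids)  # 0 new, 1 open, 2 done
    cyc <- FALSE
    visit <- function(id) {
      if (state[[id]] == 1L) { cyc <<- TRUE; return(invisible()) }
      if (state[[id]] == 2L) return(invisible())
      state[[id]] <<- 1L
      for (nx in adj[[id]]) visit(nx)
      state[[id]] <<- 2L
    }
    for (id in eids) visit(id)
    if (cyc) v <- c(v, "self-reference cycle among events")
  }
  v
}

# ---- parsing ---------------------------------------------------------------

.parse_error <- function(lineno, line, why) {
  stop(sprintf("standoff parse error at annotation line %d (%s): %s",
               lineno, why, line), call. = FALSE)
}

#' Read a standoff document from text and annotation content
#'
#' Parses the shared-task convention: each annotation line starts with `T`
#' (text-bound), `E` (event), `M` (modification), `R` (coreference) or `*`
#' (equivalence). The id is separated from the body by a tab; body fields are
#' whitespace-separated; the covered text of a `T` line follows a second tab.
#' The contents of `.a1` and `.a2` files are merged into one annotation
#' space. Discontinuous spans (`;`-separated fragments) and `N`/`A` lines are
#' rejected; in lenient mode unknown line types are skipped with a warning
#' instead of raising an error.
#'
#' @param txt_content Full document text (a single string).
#' @param ann_contents Character vector: each element is the content of one
#'   annotation file (or a single annotation line).
#' @param doc_id Document identifier to record.
#' @param lenient If `TRUE`, downgrade unknown line types to warnings.
#' @return A [standoff_document()]; an error is raised on malformed lines or
#'   dangling references.
#' @examples
#' txt <- paste0(strrep(" ", 19), "interferon regulatory factor 4")
#' doc <- read_standoff(txt,
#'   "T1\tProtein 19 49\tinterferon regulatory factor 4")
#' doc$text_bounds$T1$category
#' @export
read_standoff <- function(txt_content, ann_contents = character(),
                          doc_id = "doc", lenient = FALSE) {
  lines <- unlist(lapply(ann_contents, function(x)
    strsplit(x, "\n", fixed = TRUE)[[1]]), use.names = FALSE)
  lines <- if (length(lines)) sub("\r$", "", lines) else character()
  tbs <- list(); evs <- list(); mods <- list(); eqs <- list(); crs <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- parts[1]
    if (grepl("^T[0-9]+$", id)) {
      if (length(parts) < 2L) .parse_error(i, line, "missing body")
      body <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
      if (length(body) != 3L) {
        if (any(grepl(";", parts[2], fixed = TRUE)))
          .parse_error(i, line, "discontinuous spans are not supported")
        .parse_error(i, line, "expected 'category begin end'")
      }
      begin <- suppressWarnings(as.integer(body[2]))
      end <- suppressWarnings(as.integer(body[3]))
      if (is.na(begin) || is.na(end)) .parse_error(i, line, "non-integer offsets")
      covered <- if (length(parts) >= 3L) {
        paste(parts[3:length(parts)], collapse = "\t")
      } else {
        substr0(txt_content, begin, end)
      }
      tbs[[length(tbs) + 1L]] <- text_bound(id, body[1], begin, end, covered)
    } else if (grepl("^E[0-9]+$", id)) {
      if (length(parts) < 2L) .parse_error(i, line, "missing body")
      body <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
      kv <- strsplit(body, ":", fixed = TRUE)
      if (any(lengths(kv) != 2L)) .parse_error(i, line, "expected Role:Target fields")
      roles <- vapply(kv, `[[`, "", 1L)
      targets <- vapply(kv, `[[`, "", 2L)
      evs[[length(evs) + 1L]] <- standoff_event(
        id, roles[1], targets[1],
        data.frame(role = roles[-1], target = targets[-1],
                   stringsAsFactors = FALSE))
    } else if (grepl("^M[0-9]+$", id)) {
      body <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
      if (length(body) != 2L) .parse_error(i, line, "expected 'Kind Event'")
      mods[[length(mods) + 1L]] <- standoff_modification(id, body[1], body[2])
    } else if (grepl("^R[0-9]+$", id)) {
      body <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
      if (length(body) != 3L || body[1] != "Coreference")
        .parse_error(i, line, "expected 'Coreference Subject:Tx Object:Ty'")
      sub_ <- strsplit(body[2], ":", fixed = TRUE)[[1]]
      obj <- strsplit(body[3], ":", fixed = TRUE)[[1]]
      if (length(sub_) != 2L || sub_[1] != "Subject" ||
          length(obj) != 2L || obj[1] != "Object")
        .parse_error(i, line, "expected Subject:/Object: fields")
      crs[[length(crs) + 1L]] <- coref_link(id, sub_[2], obj[2])
    } else if (id == "*") {
      body <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
      if (body[1] != "Equiv" || length(body) < 3L)
        .parse_error(i, line, "expected 'Equiv T.. T..'")
      eqs[[length(eqs) + 1L]] <- equiv_group(body[-1])
    } else {
      if (lenient) {
        warning(sprintf("skipping unknown annotation line %d: %s", i, line))
      } else {
        .parse_error(i, line, "unknown line type")
      }
    }
  }
  doc <- standoff_document(doc_id, txt_content, tbs, evs, mods, eqs, crs)
  viol <- validate_standoff(doc)
  refs <- grep("unresolved", viol, value = TRUE)
  if (length(refs)) {
    stop(sprintf("standoff reference error: %s", paste(refs, collapse = "; ")),
         call. = FALSE)
  }
  other <- setdiff(viol, refs)
  if (length(other)) {
    stop(sprintf("standoff validation error: %s", paste(other, collapse = "; ")),
         call. = FALSE)
  }
  doc
}

# ---- serialization ---------------------------------------------------------

.fmt_text_bound <- function(tb) {
  sprintf("%s\t%s %d %d\t%s", tb$id, tb$category, tb$begin, tb$end, tb$text)
}

.fmt_event <- function(ev) {
  fields <- sprintf("%s:%s", ev$category, ev$trigger)
  if (nrow(ev$args)) {
    fields <- c(fields, sprintf("%s:%s", ev$args$role, ev$args$target))
  }
  sprintf("%s\t%s", ev$id, paste(fields, collapse = " "))
}

#' Serialize a standoff document
#'
#' Emits the canonical form: id, tab, space-separated body fields, and (for
#' text-bounds) a tab followed by the covered text. Lines are ordered
#' deterministically: `T` lines in numeric id order, then `E`, `M`, `R`
#' (numeric id order each), then `*Equiv` lines. The `a1`/`a2` split follows
#' the shared-task convention: entities never referenced as an event trigger
#' go to `a1`; triggers and all relational annotations go to `a2`.
#'
#' @param doc A valid [standoff_document()].
#' @return A list with elements `txt` (document text), `ann` (all annotation
#'   lines as one string), `a1` and `a2` (the split annotation contents).
#' @export
write_standoff <- function(doc) {
  viol <- validate_standoff(doc)
  if (length(viol)) {
    stop(sprintf("standoff validation error: %s", paste(viol, collapse = "; ")),
         call. = FALSE)
  }
  ord <- function(lst) lst[order(.numeric_id(names(lst)))]
  tbs <- ord(doc$text_bounds)
  trig_ids <- unique(vapply(doc$events, `[[`, "", "trigger"))
  t_lines <- vapply(tbs, .fmt_text_bound, character(1))
  e_lines <- vapply(ord(doc$events), .fmt_event, character(1))
  m_lines <- vapply(ord(doc$modifications), function(m)
    sprintf("%s\t%s %s", m$id, m$kind, m$target), character(1))
  r_lines <- vapply(ord(doc$coreferences), function(r)
    sprintf("%s\tCoreference Subject:%s Object:%s", r$id, r$subject, r$object),
    character(1))
  q_lines <- vapply(doc$equivalences, function(g)
    sprintf("*\tEquiv %s",
            paste(g$members[order(.numeric_id(g$members))], collapse = " ")),
    character(1))
  all_lines <- c(t_lines, e_lines, m_lines, r_lines, q_lines)
  a1_mask <- names(tbs) %in% setdiff(names(tbs), trig_ids)
  a1 <- t_lines[a1_mask]
  a2 <- c(t_lines[!a1_mask], e_lines, m_lines, r_lines, q_lines)
  join <- function(x) if (length(x)) paste0(paste(x, collapse = "\n"), "\n") else ""
  list(txt = doc$text, ann = join(all_lines), a1 = join(a1), a2 = join(a2))
}

# ---- directory io ----------------------------------------------------------

#' Read a directory of standoff documents
#'
#' Pairs `<docid>.txt` with `<docid>.a1`/`<docid>.a2` (either may be absent)
#' by basename.
#'
#' @param dir Directory path.
#' @param lenient Passed to [read_standoff()].
#' @return Named list of [standoff_document()] objects keyed by doc id.
#' @export
read_standoff_dir <- function(dir, lenient = FALSE) {
  txts <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  docs <- lapply(txts, function(p) {
    base <- sub("\\.txt$", "", basename(p))
    anns <- character()
    for (ext in c(".a1", ".a2")) {
      ap <- file.path(dir, paste0(base, ext))
      if (file.exists(ap)) {
        anns <- c(anns, paste(readLines(ap, encoding = "UTF-8", warn = FALSE),
                              collapse = "\n"))
      }
    }
    read_standoff(.read_file(p), anns, doc_id = base, lenient = lenient)
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  docs
}

#' Write standoff documents to a directory
#'
#' @param docs A [standoff_document()] or list of them.
#' @param dir Output directory (created if absent). Files are UTF-8 with LF
#'   line endings.
#' @return Invisibly, the paths written.
#' @export
write_standoff_dir <- function(docs, dir) {
  if (inherits(docs, "standoff_document")) docs <- list(docs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (doc in docs) {
    out <- write_standoff(doc)
    base <- file.path(dir, doc$doc_id)
    .write_file(out$txt, paste0(base, ".txt"))
    .write_file(out$a1, paste0(base, ".a1"))
    .write_file(out$a2, paste0(base, ".a2"))
    paths <- c(paths, paste0(base, c(".txt", ".a1", ".a2")))
  }
  invisible(paths)
}

.read_file <- function(path) {
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

.write_file <- function(content, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nzchar(content)) {
    writeChar(content, con, eos = NULL, useBytes = FALSE)
  }
  invisible(path)
}
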