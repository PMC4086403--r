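# Silver-standard corpus generation: dictionary matches filtered against
# per-document gold concept lists, then BIO token labelling for external
# sequence-labelling trainers. The gold lists carry unique concepts per
# document (preferred names, no locations); filtering keeps a match only if
# its surface normalizes into the document's gold list for that category,
# which removes ambiguous-name false positives such as the chemical "lead"
# matching the verb "lead".

#' Construct a per-document gold concept list
#'
#' @param doc_id Document identifier.
#' @param concepts Named list, one element per category (`chemical`, `gene`,
#'   `disease`, `action`), each a character vector of concept ids or
#'   preferred names.
#' @return An object of class `gold_concept_list`.
#' @export
gold_concept_list <- function(doc_id, concepts = list()) {
  stopifnot(is.list(concepts))
  bad <- setdiff(names(concepts), .vocab_categories)
  if (length(bad)) {
    stop(sprintf("unknown gold-list category: %s", paste(bad, collapse = ",")),
         call. = FALSE)
  }
  structure(list(doc_id = doc_id, concepts = concepts),
            class = "gold_concept_list")
}

#' Read gold concept lists from a TSV file
#'
#' Format: `doc_id<TAB>category<TAB>name1|name2|...`, one line per document
#' and category.
#'
#' @param path File path.
#' @return Named list of [gold_concept_list()] objects keyed by doc id.
#' @export
read_gold_lists <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop(sprintf("gold-list parse error at line %d", which(lengths(fields) < 2L)[1]),
         call. = FALSE)
  }
  out <- list()
  for (f in fields) {
    id <- f[1]; category <- f[2]
    names_ <- if (length(f) >= 3L && nzchar(f[3])) {
      strsplit(f[3], "|", fixed = TRUE)[[1]]
    } else character()
    if (is.null(out[[id]])) out[[id]] <- gold_concept_list(id)
    out[[id]]$concepts[[category]] <- unique(c(out[[id]]$concepts[[category]],
                                               names_))
  }
  out
}

#' Write gold concept lists (or predictions) to a TSV file
#'
#' @param gold List of [gold_concept_list()] or `concept_prediction` objects.
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_gold_lists <- function(gold, path) {
  lines <- character()
  for (g in gold) {
    for (category in names(g$concepts)) {
      lines <- c(lines, sprintf("%s\t%s\t%s", g$doc_id, category,
                                paste(g$concepts[[category]], collapse = "|")))
    }
  }
  .write_file(paste0(paste(lines, collapse = "\n"),
                     if (length(lines)) "\n" else ""), path)
  invisible(path)
}

# does a normalized concept belong to the document's gold list for category?
.in_gold <- function(norm, gold, category) {
  if (is.null(norm)) return(FALSE)
  pool <- gold$concepts[[category]]
  if (is.null(pool)) return(FALSE)
  norm$concept_id %in% pool || tolower(norm$preferred_name) %in% tolower(pool)
}

#' Candidate phrases for approximate matching
#'
#' When external noun-phrase chunk spans are available they are returned
#' verbatim; otherwise all sliding windows of 1-6 tokens within sentence
#' bounds are enumerated (an n-token sentence yields
#' `sum(k=1..6) max(0, n-k+1)` windows).
#'
#' @param text Document text.
#' @param chunks Optional data frame of chunk spans with columns `begin`,
#'   `end` (0-based, end-exclusive).
#' @param max_window Maximum window width in tokens (default 6).
#' @return A data frame with columns `begin`, `end`, `text`.
#' @export
candidate_phrases <- function(text, chunks = NULL, max_window = 6L) {
  if (!is.null(chunks)) {
    stopifnot(is.data.frame(chunks), all(c("begin", "end") %in% names(chunks)))
    if (nrow(chunks) && (any(chunks$begin < 0L) || any(chunks$end > nchar(text)) ||
                         any(chunks$end <= chunks$begin))) {
      stop("chunk parse error: span outside text or empty", call. = FALSE)
    }
    return(data.frame(begin = as.integer(chunks$begin),
                      end = as.integer(chunks$end),
                      text = substr0(text, chunks$begin, chunks$end),
                      stringsAsFactors = FALSE))
  }
  toks <- tokenize_document(text)
  if (nrow(toks) == 0L) {
    return(data.frame(begin = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(toks) * max_window)
  n_out <- 0L
  for (s in unique(toks$sentence)) {
    st <- toks[toks$sentence == s, , drop = FALSE]
    n <- nrow(st)
    for (k in seq_len(min(max_window, n))) {
      for (i in seq_len(n - k + 1L)) {
        n_out <- n_out + 1L
        out[[n_out]] <- c(st$begin[i], st$end[i + k - 1L])
      }
    }
  }
  spans <- do.call(rbind, out[seq_len(n_out)])
  data.frame(begin = spans[, 1], end = spans[, 2],
             text = substr0(text, spans[, 1], spans[, 2]),
             stringsAsFactors = FALSE)
}

# leftmost-longest selection among possibly overlapping spans of one category
.resolve_overlaps <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m$begin, -(m$end - m$begin)), , drop = FALSE]
  keep <- logical(nrow(m))
  last_end <- -1L
  for (i in seq_len(nrow(m))) {
    if (m$begin[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- m$end[i]
    }
  }
  m[keep, , drop = FALSE]
}

#' Silver-annotate a document
#'
#' Runs exact matching over all categories, plus approximate matching over
#' candidate phrases for the categories in `approx_categories` (by default
#' only diseases, whose names are frequently inflected in text, e.g.
#' "leukopenic" for "leukopenia"). Every match is kept only if
#' [normalize_response()] maps its surface to a concept present in the
#' document's gold list for that category; survivors are reduced to
#' leftmost-longest non-overlapping spans per category and converted into
#' per-category BIO token labels.
#'
#' @param doc_id Document identifier.
#' @param text Document text.
#' @param vocab A [vocabulary()].
#' @param gold The document's [gold_concept_list()], or `NULL`.
#' @param threshold Approximate-match threshold (see [approximate_match()]).
#' @param approx_categories Categories receiving approximate matching.
#' @param missing_gold What to do without a gold list: `"skip"` drops all
#'   matches (all-O labels), `"keep"` keeps matches unfiltered with a
#'   warning.
#' @param chunks Optional noun-phrase chunk spans for [candidate_phrases()].
#' @return An object of class `silver_document`: `doc_id`, `text`,
#'   `annotations` (match data frame), `tokens`, and `bio_labels` (named
#'   list of per-token B/I/O label vectors, one per category).
#' @export
silver_annotate <- function(doc_id, text, vocab, gold = NULL, threshold = 1L,
                            approx_categories = "disease",
                            missing_gold = c("skip", "keep"), chunks = NULL) {
  missing_gold <- match.arg(missing_gold)
  matches <- exact_match(text, vocab)
  if (length(approx_categories)) {
    phrases <- candidate_phrases(text, chunks = chunks)
    appr <- approximate_match(phrases, vocab, threshold = threshold,
                              categories = approx_categories)
    matches <- rbind(matches, appr)
  }
  if (is.null(gold)) {
    if (missing_gold == "keep") {
      warning(sprintf("no gold list for document %s; keeping matches unfiltered",
                      doc_id))
    } else {
      matches <- matches[integer(), , drop = FALSE]
    }
  } else if (nrow(matches)) {
    ok <- vapply(seq_len(nrow(matches)), function(i) {
      norm <- normalize_response(matches$text[i], vocab,
                                 categories = matches$category[i])
      .in_gold(norm, gold, matches$category[i])
    }, logical(1))
    matches <- matches[ok, , drop = FALSE]
  }
  toks <- tokenize_document(text)
  bio <- list()
  ann <- list()
  for (category in .vocab_categories) {
    mc <- .resolve_overlaps(matches[matches$category == category, , drop = FALSE])
    ann[[length(ann) + 1L]] <- mc
    labels <- rep.int("O", nrow(toks))
    if (nrow(mc) && nrow(toks)) {
      for (i in seq_len(nrow(mc))) {
        inside <- which(toks$begin < mc$end[i] & toks$end > mc$begin[i])
        if (length(inside)) {
          labels[inside[1]] <- "B"
          if (length(inside) > 1L) labels[inside[-1]] <- "I"
        }
      }
    }
    bio[[category]] <- labels
  }
  annotations <- do.call(rbind, ann)
  annotations <- annotations[order(annotations$begin, annotations$end), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(doc_id = doc_id, text = text, annotations = annotations,
                 tokens = toks, bio_labels = bio),
            class = "silver_document")
}

#' @export
print.silver_document <- function(x, ...) {
  cat(sprintf("silver_document '%s': %d tokens, %d annotation(s)\n",
              x$doc_id, nrow(x$tokens), nrow(x$annotations)))
  invisible(x)
}

#' Emit BIO token-label lines for one category
#'
#' One `token<TAB>begin<TAB>end<TAB>label` line per token, with a blank line
#' between sentences — the input format expected by external CRF toolkits.
#'
#' @param doc A [silver_annotate()] result.
#' @param category Concept category whose labels to emit.
#' @return Character vector of lines.
#' @export
emit_bio <- function(doc, category = "chemical") {
  stopifnot(inherits(doc, "silver_document"),
            category %in% names(doc$bio_labels))
  toks <- doc$tokens
  if (nrow(toks) == 0L) return(character())
  labels <- doc$bio_labels[[category]]
  lines <- character()
  for (s in unique(toks$sentence)) {
    idx <- which(toks$sentence == s)
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", toks$text[idx],
                              toks$begin[idx], toks$end[idx], labels[idx]),
               "")
  }
  lines[-length(lines)]
}

#' Decode BIO lines back into spans
#'
#' Inverse of [emit_bio()]: contiguous `B I*` runs become spans from the
#' first token's begin to the last token's end.
#'
#' @param lines Character vector as produced by [emit_bio()].
#' @return Data frame with columns `begin`, `end`.
#' @export
decode_bio <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(begin = integer(), end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    stop("BIO parse error: expected token<TAB>begin<TAB>end<TAB>label",
         call. = FALSE)
  }
  begin <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  label <- vapply(fields, `[[`, "", 4L)
  spans <- list()
  cur <- NULL
  for (i in seq_along(label)) {
    if (label[i] == "B") {
      if (!is.null(cur)) spans[[length(spans) + 1L]] <- cur
      cur <- c(begin[i], end[i])
    } else if (label[i] == "I" && !is.null(cur)) {
      cur[2] <- end[i]
    } else if (label[i] == "O") {
      if (!is.null(cur)) spans[[length(spans) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) spans[[length(spans) + 1L]] <- cur
  if (!length(spans)) {
    return(data.frame(begin = integer(), end = integer(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, spans)
  data.frame(begin = m[, 1], end = m[, 2], stringsAsFactors = FALSE)
}

#' Collapse surviving annotations into per-document concept predictions
#'
#' Each annotation's surface is normalized via [normalize_response()] and the
#' de-duplicated preferred names are collected per category — the unit of
#' concept-level evaluation. Unmappable surfaces are omitted.
#'
#' @param doc_id Document identifier.
#' @param annotations Match data frame (e.g. `silver$annotations`).
#' @param vocab A [vocabulary()].
#' @return An object of class `concept_prediction`: `doc_id` plus `concepts`
#'   (named list of preferred-name character vectors per category).
#' @export
responses_to_concepts <- function(doc_id, annotations, vocab) {
  concepts <- list()
  if (!is.null(annotations) && nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      category <- annotations$category[i]
      norm <- normalize_response(annotations$text[i], vocab,
                                 categories = category)
      if (!is.null(norm)) {
        concepts[[category]] <- unique(c(concepts[[category]],
                                         norm$preferred_name))
      }
    }
  }
  structure(list(doc_id = doc_id, concepts = concepts),
            class = "concept_prediction")
}
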