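# Concept-level evaluation as the CTD track scored it: responses are mapped
# to preferred names directly or indirectly through synonyms
# (case-insensitive exact matching), tp/fp/fn are summed over documents per
# category, and precision/recall/F are computed once from the sums
# (micro-averaging). The combined average is the arithmetic mean of the
# per-category F-scores.

#' Map a response string to a preferred vocabulary name
#'
#' Case-insensitive equality against preferred names first, then synonyms;
#' the matched entry's preferred name is returned, or `NA` when nothing
#' matches. When one string is a shared synonym of several entries, the
#' first entry in vocabulary file order wins (with a warning).
#'
#' @param response Response string.
#' @param vocab A [vocabulary()].
#' @param categories Optional restriction of entry categories.
#' @return Preferred name, or `NA_character_`.
#' @export
map_response <- function(response, vocab, categories = NULL) {
  stopifnot(inherits(vocab, "vocabulary"))
  rows <- seq_len(nrow(vocab$surfaces))
  if (!is.null(categories)) {
    rows <- rows[vocab$entries$category[vocab$surfaces$entry] %in% categories]
  }
  if (!length(rows)) return(NA_character_)
  hit <- rows[tolower(vocab$surfaces$surface[rows]) == tolower(response)]
  if (!length(hit)) return(NA_character_)
  pref_hits <- hit[vocab$surfaces$is_preferred[hit]]
  if (length(pref_hits)) hit <- pref_hits
  ents <- unique(vocab$surfaces$entry[hit])
  if (length(ents) > 1L) {
    warning(sprintf("response '%s' maps to %d entries; keeping first in file order",
                    response, length(ents)))
  }
  vocab$entries$preferred_name[ents[1]]
}

#' Construct a concept prediction
#'
#' @param doc_id Document identifier.
#' @param concepts Named list of character vectors per category.
#' @return An object of class `concept_prediction`.
#' @export
concept_prediction <- function(doc_id, concepts = list()) {
  structure(list(doc_id = doc_id, concepts = concepts),
            class = "concept_prediction")
}

.prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0L) 0 else 100 * tp / (tp + fp)
  r <- if (tp + fn == 0L) 0 else 100 * tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f_score = f)
}

#' Micro-averaged concept-level precision/recall/F
#'
#' Per category, both the gold names and the predicted names of every
#' document are mapped through the vocabulary ([map_response()]), duplicates
#' collapse to sets, and tp/fp/fn are summed over all documents before P, R
#' and F are formed (micro-averaging). A predicted response that maps to no
#' vocabulary entry can never match a gold preferred name and therefore
#' counts as a false positive in its category. The combined F is the
#' arithmetic mean of the per-category F-scores.
#'
#' @param gold List of [gold_concept_list()] objects.
#' @param pred List of `concept_prediction` objects; every predicted doc id
#'   must appear in the gold list (an error names any that does not).
#' @param vocab A [vocabulary()].
#' @param categories Categories to score; defaults to every category present
#'   in the gold lists.
#' @return An object of class `eval_report`: per-category data frame with
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f_score` (percent), plus
#'   `combined_f`.
#' @examples
#' v <- vocabulary(data.frame(concept_id = c("C1", "C2", "C3"),
#'                            category = "chemical",
#'                            preferred_name = c("a", "b", "c")))
#' g <- list(gold_concept_list("d1", list(chemical = c("a", "b"))))
#' p <- list(concept_prediction("d1", list(chemical = c("a", "c"))))
#' micro_prf(g, p, v)$per_category  # P = R = F = 50
#' @export
micro_prf <- function(gold, pred, vocab, categories = NULL) {
  gold_ids <- vapply(gold, `[[`, "", "doc_id")
  pred_ids <- vapply(pred, `[[`, "", "doc_id")
  missing <- setdiff(pred_ids, gold_ids)
  if (length(missing)) {
    stop(sprintf("predicted document(s) absent from gold: %s",
                 paste(missing, collapse = ",")), call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- unique(unlist(lapply(gold, function(g) names(g$concepts))))
    categories <- intersect(.vocab_categories, categories)
  }
  map_set <- function(names_, category) {
    if (!length(names_)) return(character())
    mapped <- vapply(names_, function(x) {
      m <- map_response(x, vocab, categories = category)
      if (is.na(m)) paste0("\rUNMAPPED\r", tolower(x)) else m
    }, character(1), USE.NAMES = FALSE)
    unique(mapped)
  }
  rows <- list()
  for (category in categories) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (gi in seq_along(gold)) {
      g <- map_set(gold[[gi]]$concepts[[category]], category)
      pidx <- which(pred_ids == gold_ids[gi])
      p <- if (length(pidx)) {
        map_set(pred[[pidx[1]]]$concepts[[category]], category)
      } else character()
      tp <- tp + length(intersect(g, p))
      fp <- fp + length(setdiff(p, g))
      fn <- fn + length(setdiff(g, p))
    }
    rows[[category]] <- c(tp = tp, fp = fp, fn = fn, .prf(tp, fp, fn))
  }
  per_category <- as.data.frame(do.call(rbind, rows))
  per_category$category <- names(rows)
  per_category <- per_category[, c("category", "tp", "fp", "fn",
                                   "precision", "recall", "f_score")]
  rownames(per_category) <- NULL
  structure(list(per_category = per_category,
                 combined_f = mean(per_category$f_score)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  df <- x$per_category
  df$precision <- sprintf("%.2f", df$precision)
  df$recall <- sprintf("%.2f", df$recall)
  df$f_score <- sprintf("%.2f", df$f_score)
  print(df, row.names = FALSE)
  cat(sprintf("combined average F: %.2f\n", x$combined_f))
  invisible(x)
}
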