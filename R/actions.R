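# Document-level multilabel action-term assignment. Action terms (53 in the
# CTD label set) rarely appear verbatim in abstracts, so the document is
# described by (1) boolean verb-variant match flags from a biomedical verb
# lexicon and (2) weighted sentence-level co-occurrence of a verb variant
# with at least one chemical and one gene mention, and each label gets an
# independent thresholded one-vs-all scorer.

#' Read a verb lexicon from a TSV file
#'
#' Format: `lemma<TAB>variant1|variant2|...`. Every variant maps to exactly
#' one lemma in the index; a variant listed under two lemmas is an error.
#'
#' @param path File path.
#' @return An object of class `verb_lexicon`: list with `lemmas` (character
#'   vector) and `variant_index` (named character vector variant -> lemma).
#' @export
read_verb_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lemmas <- vapply(fields, `[[`, "", 1L)
  variants <- lapply(seq_along(fields), function(i) {
    v <- if (length(fields[[i]]) >= 2L && nzchar(fields[[i]][2])) {
      strsplit(fields[[i]][2], "|", fixed = TRUE)[[1]]
    } else character()
    unique(c(lemmas[i], v))
  })
  verb_lexicon(setNames(variants, lemmas))
}

#' Construct a verb lexicon
#'
#' @param entries Named list: lemma -> character vector of surface variants
#'   (the lemma itself is always included as a variant).
#' @return An object of class `verb_lexicon`.
#' @export
verb_lexicon <- function(entries) {
  stopifnot(is.list(entries), !is.null(names(entries)), all(nzchar(names(entries))))
  lemmas <- names(entries)
  entries <- lapply(seq_along(entries), function(i)
    unique(tolower(c(lemmas[i], entries[[i]]))))
  names(entries) <- lemmas
  all_variants <- unlist(entries, use.names = FALSE)
  if (anyDuplicated(all_variants)) {
    dup <- unique(all_variants[duplicated(all_variants)])
    stop(sprintf("variant(s) map to more than one lemma: %s",
                 paste(dup, collapse = ",")), call. = FALSE)
  }
  idx <- setNames(rep(lemmas, lengths(entries)), all_variants)
  structure(list(lemmas = lemmas, entries = entries, variant_index = idx),
            class = "verb_lexicon")
}

#' Extract action-term features from a document
#'
#' Two feature families per lexicon lemma: `match_flags[l]` is `TRUE` iff any
#' variant of lemma `l` occurs as a whole token; `cooc_weights[l]`
#' accumulates, over sentences containing a variant of `l` together with at
#' least one chemical and one gene mention, a proximity weight `1/(1+d)`
#' where `d` is the token distance from the verb to the nearer of the
#' closest chemical and the closest gene. Accumulated weights are normalized
#' by their maximum over all lemmas, so they lie in `[0,1]` and are invariant
#' under document duplication.
#'
#' @param tokens Token data frame from [tokenize_document()] (columns
#'   `begin`, `end`, `text`, `sentence`).
#' @param chem_spans,gene_spans Data frames with `begin`/`end` columns of
#'   recognized chemical and gene mentions (any tagger's output).
#' @param lexicon A [verb_lexicon()].
#' @param normalize `"max"` (default) divides by the maximum accumulated
#'   weight; `"tokens"` divides by the document token count.
#' @param weight_fun Proximity weight as a function of token distance.
#' @return An object of class `action_features`: list with logical
#'   `match_flags` and numeric `cooc_weights`, both named by lemma.
#' @export
extract_action_features <- function(tokens, chem_spans = NULL,
                                    gene_spans = NULL, lexicon,
                                    normalize = c("max", "tokens"),
                                    weight_fun = function(d) 1 / (1 + d)) {
  stopifnot(inherits(lexicon, "verb_lexicon"))
  normalize <- match.arg(normalize)
  if (!length(lexicon$lemmas)) {
    stop("verb lexicon is empty", call. = FALSE)
  }
  lemmas <- lexicon$lemmas
  flags <- setNames(rep.int(FALSE, length(lemmas)), lemmas)
  weights <- setNames(rep.int(0, length(lemmas)), lemmas)
  if (is.null(tokens) || nrow(tokens) == 0L) {
    return(structure(list(match_flags = flags, cooc_weights = weights),
                     class = "action_features"))
  }
  low <- tolower(tokens$text)
  verb_lemma <- lexicon$variant_index[low]  # NA where token is no variant
  flags[unique(verb_lemma[!is.na(verb_lemma)])] <- TRUE

  in_spans <- function(spans) {
    if (is.null(spans) || !nrow(spans)) return(rep.int(FALSE, nrow(tokens)))
    hit <- rep.int(FALSE, nrow(tokens))
    for (i in seq_len(nrow(spans))) {
      hit <- hit | (tokens$begin < spans$end[i] & tokens$end > spans$begin[i])
    }
    hit
  }
  is_chem <- in_spans(chem_spans)
  is_gene <- in_spans(gene_spans)

  for (s in unique(tokens$sentence)) {
    idx <- which(tokens$sentence == s)
    verbs <- idx[!is.na(verb_lemma[idx])]
    chems <- idx[is_chem[idx]]
    genes <- idx[is_gene[idx]]
    if (!length(verbs) || !length(chems) || !length(genes)) next
    pos <- seq_along(idx)
    names(pos) <- idx
    for (v in verbs) {
      vp <- pos[[as.character(v)]]
      d_chem <- min(abs(pos[as.character(chems)] - vp))
      d_gene <- min(abs(pos[as.character(genes)] - vp))
      d <- min(d_chem, d_gene)
      l <- verb_lemma[v]
      weights[l] <- weights[l] + weight_fun(d)
    }
  }
  if (normalize == "max") {
    mx <- max(weights)
    if (mx > 0) weights <- weights / mx
  } else {
    weights <- weights / max(1L, nrow(tokens))
  }
  weights[!flags] <- 0
  structure(list(match_flags = flags, cooc_weights = weights),
            class = "action_features")
}

# feature vector as numeric: flags then co-occurrence weights
.fv_numeric <- function(fv) {
  c(as.numeric(fv$match_flags), fv$cooc_weights)
}

#' Train one-vs-all label scorers (regularized least squares)
#'
#' One linear scorer per label is fit label-vs-rest by ridge-regularized
#' least squares on +1/-1 targets (the intercept is unpenalized). The fit is
#' closed-form, so training is deterministic and entirely independent of
#' example order; on perfectly contradictory data (identical feature vectors
#' appearing as both positive and negative in equal numbers) the fitted
#' score is exactly zero, i.e. chance, and no label fires under the strict
#' decision threshold. A label with no positive (or no negative) example
#' yields a scorer that never exceeds the decision threshold, with a
#' warning.
#'
#' @param examples List of training examples, each a list with `features`
#'   (an [extract_action_features()] result) and `labels` (character vector,
#'   possibly empty).
#' @param labels Full label vocabulary (the CTD action-term set has 53).
#' @param seed Integer seed, kept for interface stability; the closed-form
#'   fit involves no randomness.
#' @param lambda Ridge penalty on the feature weights.
#' @return An object of class `label_scorers`: per-label weight vectors and
#'   biases plus the decision `threshold` (0).
#' @export
train_one_vs_all <- function(examples, labels, seed = 1L, lambda = 0.1) {
  stopifnot(length(examples) >= 1L, length(labels) >= 1L, lambda > 0)
  X <- t(vapply(examples, function(e) .fv_numeric(e$features),
                numeric(length(.fv_numeric(examples[[1]]$features)))))
  y_sets <- lapply(examples, `[[`, "labels")
  p <- ncol(X)
  Xa <- cbind(1, X)
  A <- crossprod(Xa) + lambda * diag(p + 1L)
  A[1L, 1L] <- A[1L, 1L] - lambda
  scorers <- list()
  for (lab in labels) {
    y <- ifelse(vapply(y_sets, function(s) lab %in% s, logical(1)), 1, -1)
    if (all(y == 1) || all(y == -1)) {
      warning(sprintf("label '%s' has no %s example; scorer disabled", lab,
                      if (all(y == 1)) "negative" else "positive"))
      scorers[[lab]] <- list(w = rep.int(0, p), b = -1)
      next
    }
    wb <- solve(A, crossprod(Xa, y))
    scorers[[lab]] <- list(w = as.numeric(wb[-1L]), b = as.numeric(wb[1L]))
  }
  structure(list(scorers = scorers, labels = labels, threshold = 0),
            class = "label_scorers")
}

#' Score a feature vector against all label scorers
#'
#' @param fv An [extract_action_features()] result.
#' @param scorers A [train_one_vs_all()] result.
#' @return Named numeric vector of per-label scores.
#' @export
score_labels <- function(fv, scorers) {
  x <- .fv_numeric(fv)
  vapply(scorers$scorers, function(s) sum(s$w * x) + s$b, numeric(1))
}

#' Multilabel decision by thresholded one-vs-all scores
#'
#' Returns every label whose score strictly exceeds the threshold; the set
#' may be empty and is never forced to a single label. The decision is
#' monotone in the threshold (raising it can only shrink the set).
#'
#' @param fv An [extract_action_features()] result.
#' @param scorers A [train_one_vs_all()] result.
#' @param threshold Decision threshold; defaults to the scorers' stored one.
#' @return Character vector of assigned labels.
#' @export
decide_labels <- function(fv, scorers, threshold = NULL) {
  if (is.null(threshold)) threshold <- scorers$threshold
  sc <- score_labels(fv, scorers)
  names(sc)[sc > threshold]
}
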