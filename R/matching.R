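# Dictionary-driven concept matching: canonical token forms, exact
# whole-token matching, approximate matching by stemmed-token overlap, and
# best-entry normalization of recognized responses.

#' Canonicalize a phrase into its matching form
#'
#' The canonical form of a phrase is obtained by case normalization,
#' tokenization on non-alphanumeric boundaries, stop-word removal, stemming,
#' and alphabetical reordering of the stems. Two phrases match approximately
#' when their canonical forms share tokens: "injured by stun gun" and
#' "Stun Gun Injury" both canonicalize to `gun injur stun`.
#'
#' @param phrase Input string.
#' @param stopwords Character vector of lowercase stop words.
#' @param stemmer Function mapping a character vector of lowercase tokens to
#'   stems.
#' @return An object of class `canonical_form`: list with `tokens` (sorted
#'   stems; possibly empty) and `source` (the original string).
#' @examples
#' canonicalize("injured by stun gun")$tokens  # "gun" "injur" "stun"
#' @export
canonicalize <- function(phrase, stopwords = default_stopwords(),
                         stemmer = default_stemmer) {
  stopifnot(is.character(phrase), length(phrase) == 1L)
  toks <- tokenize_text(tolower(phrase))$text
  toks <- toks[!toks %in% stopwords]
  if (length(toks)) {
    toks <- sort(.stem_fixpoint(toks, stemmer), method = "radix")
  }
  structure(list(tokens = toks, source = phrase), class = "canonical_form")
}

# stem to a fixpoint: suffix stripping can expose a further suffix
# ("regulatory" -> "regulator" -> "regul"), and iterating makes
# canonicalization idempotent for any stemmer
.stem_fixpoint <- function(tokens, stemmer) {
  for (i in 1:5) {
    stems <- stemmer(tokens)
    if (identical(stems, tokens)) break
    tokens <- stems
  }
  tokens
}

#' Number of common tokens between two canonical forms
#'
#' The score is the size of the multiset intersection of the two token lists
#' (each shared token counted up to its minimum multiplicity); it is
#' symmetric and equals the token count on identical forms.
#'
#' @param a,b [canonicalize()] results.
#' @return Non-negative integer.
#' @export
overlap_score <- function(a, b) {
  stopifnot(inherits(a, "canonical_form"), inherits(b, "canonical_form"))
  .overlap_tokens(a$tokens, b$tokens)
}

.overlap_tokens <- function(x, y) {
  if (!length(x) || !length(y)) return(0L)
  tx <- table(x); ty <- table(y)
  shared <- intersect(names(tx), names(ty))
  if (!length(shared)) return(0L)
  sum(pmin(as.integer(tx[shared]), as.integer(ty[shared])))
}

# deterministic preference among competing entries: longer preferred name
# first, then lexicographic concept id
.entry_preference_order <- function(vocab, entry_idx) {
  pn <- vocab$entries$preferred_name[entry_idx]
  cid <- vocab$entries$concept_id[entry_idx]
  order(-nchar(pn), cid, method = "radix")
}

.empty_matches <- function() {
  data.frame(begin = integer(), end = integer(), text = character(),
             concept_id = character(), category = character(),
             score = integer(), mode = character(), stringsAsFactors = FALSE)
}

#' Exact dictionary matching
#'
#' Finds whole-token, case-insensitive occurrences of any vocabulary surface
#' form (preferred names and synonyms). Among overlapping candidates the
#' leftmost match wins, and at equal start positions the longest; the
#' remaining text is scanned after the accepted match, so results never
#' overlap. Ambiguous names produce matches like any other (the chemical
#' "lead" will match the verb "lead"); false positives are expected to be
#' removed downstream by gold-list filtering.
#'
#' @param text Document text.
#' @param vocab A [vocabulary()].
#' @param categories Optional character vector restricting the entry
#'   categories considered.
#' @return A data frame of matches with columns `begin`, `end`, `text`,
#'   `concept_id`, `category`, `score` (token count of the matched name) and
#'   `mode` (`"exact"`).
#' @export
exact_match <- function(text, vocab, categories = NULL) {
  stopifnot(inherits(vocab, "vocabulary"))
  toks <- tokenize_text(text)
  if (nrow(toks) == 0L || nrow(vocab$surfaces) == 0L) return(.empty_matches())
  keep <- if (is.null(categories)) {
    seq_len(nrow(vocab$surfaces))
  } else {
    which(vocab$entries$category[vocab$surfaces$entry] %in% categories)
  }
  if (!length(keep)) return(.empty_matches())
  # index surface token sequences by first token
  surf_tokens <- lapply(vocab$surfaces$surface[keep],
                        function(s) tokenize_text(tolower(s))$text)
  nonempty <- lengths(surf_tokens) > 0L
  keep <- keep[nonempty]; surf_tokens <- surf_tokens[nonempty]
  if (!length(keep)) return(.empty_matches())
  first_tok <- vapply(surf_tokens, `[[`, "", 1L)
  by_first <- split(seq_along(keep), first_tok)

  low <- tolower(toks$text)
  n <- nrow(toks)
  out <- list()
  i <- 1L
  while (i <= n) {
    cands <- by_first[[low[i]]]
    best_len <- 0L; best_rows <- integer()
    for (ci in cands) {
      st <- surf_tokens[[ci]]
      k <- length(st)
      if (k < best_len || i + k - 1L > n) next
      if (identical(low[i:(i + k - 1L)], st)) {
        if (k > best_len) {
          best_len <- k; best_rows <- ci
        } else {
          best_rows <- c(best_rows, ci)
        }
      }
    }
    if (best_len > 0L) {
      entry_idx <- vocab$surfaces$entry[keep[best_rows]]
      pick <- entry_idx[.entry_preference_order(vocab, entry_idx)[1]]
      b <- toks$begin[i]; e <- toks$end[i + best_len - 1L]
      out[[length(out) + 1L]] <- data.frame(
        begin = b, end = e, text = substr0(text, b, e),
        concept_id = vocab$entries$concept_id[pick],
        category = vocab$entries$category[pick],
        score = best_len, mode = "exact", stringsAsFactors = FALSE)
      i <- i + best_len
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(.empty_matches())
  do.call(rbind, out)
}

# surface rows sharing at least one canonical token with `tokens`
.candidate_surfaces <- function(vocab, tokens) {
  unique(unlist(lapply(unique(tokens), function(tok) vocab$token_index[[tok]]),
                use.names = FALSE))
}

#' Approximate matching by stemmed-token overlap
#'
#' For each candidate phrase, the canonical form is compared against every
#' vocabulary surface form sharing at least one token; the score is the
#' common-token count and a phrase matches when its best score is strictly
#' greater than `threshold`. The emitted span is the minimal contiguous
#' sub-span of the phrase covering the tokens in common. Per phrase only the
#' highest-scoring entry is kept (ties broken by longer preferred name, then
#' lexicographic concept id).
#'
#' @param phrases Data frame of candidate phrases with columns `begin`,
#'   `end`, `text` (e.g. from [candidate_phrases()]).
#' @param vocab A [vocabulary()].
#' @param threshold Integer; a match requires `score > threshold`. Default 1,
#'   i.e. at least two common tokens.
#' @param categories Optional restriction of entry categories.
#' @return A data frame of matches (`mode = "approximate"`), one row per
#'   matching phrase.
#' @export
approximate_match <- function(phrases, vocab, threshold = 1L,
                              categories = NULL) {
  stopifnot(inherits(vocab, "vocabulary"), threshold >= 1L)
  if (!is.data.frame(phrases) || nrow(phrases) == 0L) return(.empty_matches())
  cat_ok <- if (is.null(categories)) {
    rep.int(TRUE, nrow(vocab$entries))
  } else {
    vocab$entries$category %in% categories
  }
  out <- list()
  for (pi in seq_len(nrow(phrases))) {
    ptext <- phrases$text[pi]
    pcanon <- canonicalize(ptext, vocab$stopwords, vocab$stemmer)
    if (!length(pcanon$tokens)) next
    rows <- .candidate_surfaces(vocab, pcanon$tokens)
    rows <- rows[cat_ok[vocab$surfaces$entry[rows]]]
    if (!length(rows)) next
    scores <- vapply(rows, function(ri)
      .overlap_tokens(pcanon$tokens, vocab$canon[[ri]]$tokens), integer(1))
    # best score per entry
    entry_idx <- vocab$surfaces$entry[rows]
    best <- max(scores)
    if (best <= threshold) next
    top_entries <- unique(entry_idx[scores == best])
    pick <- top_entries[.entry_preference_order(vocab, top_entries)[1]]
    pick_row <- rows[entry_idx == pick & scores == best][1]
    # minimal contiguous sub-span covering the common tokens
    ptoks <- tokenize_text(ptext)
    ptoks2 <- ptoks[!tolower(ptoks$text) %in% vocab$stopwords, , drop = FALSE]
    stems <- .stem_fixpoint(tolower(ptoks2$text), vocab$stemmer)
    common <- intersect(stems, vocab$canon[[pick_row]]$tokens)
    hit <- stems %in% common
    if (!any(hit)) next
    b <- phrases$begin[pi] + min(ptoks2$begin[hit])
    e <- phrases$begin[pi] + max(ptoks2$end[hit])
    out[[length(out) + 1L]] <- data.frame(
      begin = b, end = e, text = substr0(ptext, min(ptoks2$begin[hit]),
                                         max(ptoks2$end[hit])),
      concept_id = vocab$entries$concept_id[pick],
      category = vocab$entries$category[pick],
      score = best, mode = "approximate", stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_matches())
  do.call(rbind, out)
}

#' Normalize a recognized response to its best vocabulary entry
#'
#' A response equal (case-insensitively) to any preferred name or synonym is
#' returned directly. Otherwise the response is canonicalized and the entry
#' with the highest common-token score is returned; `NULL` when the best
#' score is zero.
#'
#' @param response_text Recognized span text.
#' @param vocab A [vocabulary()].
#' @param categories Optional restriction of entry categories.
#' @return A list with `concept_id` and `preferred_name`, or `NULL`.
#' @examples
#' v <- vocabulary(data.frame(concept_id = "D013", category = "disease",
#'                            preferred_name = "Stun Gun Injury"))
#' normalize_response("injured by stun gun", v)$preferred_name
#' @export
normalize_response <- function(response_text, vocab, categories = NULL) {
  stopifnot(inherits(vocab, "vocabulary"))
  if (nrow(vocab$surfaces) == 0L) return(NULL)
  cat_ok <- if (is.null(categories)) {
    rep.int(TRUE, nrow(vocab$entries))
  } else {
    vocab$entries$category %in% categories
  }
  rows <- which(cat_ok[vocab$surfaces$entry])
  if (!length(rows)) return(NULL)
  # direct case-insensitive hit wins regardless of approximate scores
  direct <- rows[tolower(vocab$surfaces$surface[rows]) ==
                   tolower(response_text)]
  if (length(direct)) {
    ents <- unique(vocab$surfaces$entry[direct])
    pick <- ents[1]  # vocabulary file order on shared-synonym ties
    if (length(ents) > 1L) {
      warning(sprintf("response '%s' maps to multiple entries; keeping %s",
                      response_text, vocab$entries$concept_id[pick]))
    }
    return(list(concept_id = vocab$entries$concept_id[pick],
                preferred_name = vocab$entries$preferred_name[pick]))
  }
  rcanon <- canonicalize(response_text, vocab$stopwords, vocab$stemmer)
  if (!length(rcanon$tokens)) return(NULL)
  cand <- intersect(.candidate_surfaces(vocab, rcanon$tokens), rows)
  if (!length(cand)) return(NULL)
  scores <- vapply(cand, function(ri)
    .overlap_tokens(rcanon$tokens, vocab$canon[[ri]]$tokens), integer(1))
  best <- max(scores)
  if (best == 0L) return(NULL)
  top_entries <- unique(vocab$surfaces$entry[cand[scores == best]])
  pick <- top_entries[.entry_preference_order(vocab, top_entries)[1]]
  list(concept_id = vocab$entries$concept_id[pick],
       preferred_name = vocab$entries$preferred_name[pick])
}
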