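# Controlled vocabularies: concept entries (id, category, preferred name,
# synonyms) with precomputed canonical token forms for matching.

.vocab_categories <- c("chemical", "gene", "disease", "action")

#' Construct a vocabulary from a data frame of entries
#'
#' Canonical token forms of every surface form (preferred name and synonyms)
#' are precomputed at construction, together with a token inverted index used
#' by the approximate matcher.
#'
#' @param entries Data frame with columns `concept_id`, `category`,
#'   `preferred_name` and a list-column `synonyms` (character vectors; may be
#'   empty).
#' @param stopwords Character vector used during canonicalization.
#' @param stemmer Token-stemming function, by default [default_stemmer()].
#' @return An object of class `vocabulary`.
#' @export
vocabulary <- function(entries, stopwords = default_stopwords(),
                       stemmer = default_stemmer) {
  stopifnot(is.data.frame(entries),
            all(c("concept_id", "category", "preferred_name") %in% names(entries)))
  if (!"synonyms" %in% names(entries)) {
    entries$synonyms <- replicate(nrow(entries), character(), simplify = FALSE)
  }
  if (anyDuplicated(entries$concept_id)) {
    stop("concept_id values must be unique per vocabulary", call. = FALSE)
  }
  if (any(!nzchar(entries$preferred_name))) {
    stop("preferred_name must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unique(entries$category), .vocab_categories)
  if (length(bad)) {
    stop(sprintf("unknown vocabulary category: %s (expected %s)",
                 paste(bad, collapse = ","),
                 paste(.vocab_categories, collapse = "/")), call. = FALSE)
  }
  # one row per surface form
  surfaces <- do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
    forms <- c(entries$preferred_name[i], entries$synonyms[[i]])
    data.frame(entry = i, surface = forms,
               is_preferred = c(TRUE, rep.int(FALSE, length(forms) - 1L)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(surfaces)) {
    surfaces <- data.frame(entry = integer(), surface = character(),
                           is_preferred = logical(), stringsAsFactors = FALSE)
  }
  canon <- lapply(surfaces$surface, canonicalize,
                  stopwords = stopwords, stemmer = stemmer)
  # inverted index: canonical token -> surface row indices
  index <- new.env(parent = emptyenv())
  for (i in seq_along(canon)) {
    for (tok in unique(canon[[i]]$tokens)) {
      index[[tok]] <- c(index[[tok]], i)
    }
  }
  structure(list(entries = entries, surfaces = surfaces, canon = canon,
                 token_index = index, stopwords = stopwords,
                 stemmer = stemmer),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("vocabulary: %d entries (%s), %d surface forms\n",
              nrow(x$entries),
              paste(sprintf("%s=%d", names(table(x$entries$category)),
                            table(x$entries$category)), collapse = ", "),
              nrow(x$surfaces)))
  invisible(x)
}

#' Read a vocabulary from a TSV file
#'
#' Expected columns: `concept_id<TAB>category<TAB>preferred_name<TAB>`
#' `synonym1|synonym2|...` (the synonym column may be empty or absent).
#'
#' @param path File path.
#' @inheritParams vocabulary
#' @return A [vocabulary()].
#' @export
read_vocabulary <- function(path, stopwords = default_stopwords(),
                            stemmer = default_stemmer) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop(sprintf("vocabulary parse error at line %d: expected at least 3 fields",
                 which(lengths(fields) < 3L)[1]), call. = FALSE)
  }
  entries <- data.frame(
    concept_id = vapply(fields, `[[`, "", 1L),
    category = vapply(fields, `[[`, "", 2L),
    preferred_name = vapply(fields, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  entries$synonyms <- lapply(fields, function(f) {
    if (length(f) < 4L || !nzchar(f[4])) return(character())
    strsplit(f[4], "|", fixed = TRUE)[[1]]
  })
  vocabulary(entries, stopwords = stopwords, stemmer = stemmer)
}

#' Write a vocabulary to a TSV file
#'
#' @param vocab A [vocabulary()].
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_vocabulary <- function(vocab, path) {
  e <- vocab$entries
  syn <- vapply(e$synonyms, paste, "", collapse = "|")
  lines <- sprintf("%s\t%s\t%s\t%s", e$concept_id, e$category,
                   e$preferred_name, syn)
  .write_file(paste0(paste(lines, collapse = "\n"),
                     if (length(lines)) "\n" else ""), path)
  invisible(path)
}
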