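# Porter stemmer (1980), written out in full because no stemming package is
# part of this package's dependency set. The stemmer is only ever applied to
# lowercase alphabetic tokens; anything containing a non-letter is returned
# unchanged. A small cache keeps repeated stemming of the same token cheap.

# A consonant is a letter other than a,e,i,o,u and other than y preceded by
# a consonant (so "y" at word start, or after a vowel, is a consonant).
.porter_cons_mask <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# m = number of VC sequences in the [C](VC)^m[V] decomposition of the stem
.porter_measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cons <- .porter_cons_mask(strsplit(stem, "", fixed = TRUE)[[1]])
  # count transitions vowel -> consonant
  sum(!cons[-length(cons)] & cons[-1L]) + 0L
}

.porter_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.porter_cons_mask(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (chars[n] != chars[n - 1L]) return(FALSE)
  cons <- .porter_cons_mask(chars)
  cons[n]
}

# *o condition: stem ends cvc where the final consonant is not w, x or y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  cons <- .porter_cons_mask(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(chars[n] %in% c("w", "x", "y"))
}

.porter_ends <- function(word, suffix) {
  n <- nchar(word); s <- nchar(suffix)
  n > s && substring(word, n - s + 1L, n) == suffix
}

.porter_chop <- function(word, suffix) {
  substring(word, 1L, nchar(word) - nchar(suffix))
}

# try rules (suffix -> replacement) requiring measure(stem) > min_m; returns
# the word after the FIRST rule whose suffix matches (Porter semantics: the
# longest-match rule fires and no other rule in the step is tried), or NULL
.porter_step_rules <- function(word, rules, min_m) {
  for (k in seq_along(rules)) {
    suf <- names(rules)[k]
    if (.porter_ends(word, suf)) {
      stem <- .porter_chop(word, suf)
      if (.porter_measure(stem) > min_m) {
        return(paste0(stem, rules[[k]]))
      }
      return(word)
    }
  }
  NULL
}

.porter_stem_one <- function(word) {
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)

  # step 1a
  if (.porter_ends(word, "sses")) {
    word <- .porter_chop(word, "es")
  } else if (.porter_ends(word, "ies")) {
    word <- paste0(.porter_chop(word, "ies"), "i")
  } else if (!.porter_ends(word, "ss") && .porter_ends(word, "s")) {
    word <- .porter_chop(word, "s")
  }

  # step 1b
  fixup <- FALSE
  if (.porter_ends(word, "eed")) {
    stem <- .porter_chop(word, "eed")
    if (.porter_measure(stem) > 0L) word <- paste0(stem, "ee")
  } else if (.porter_ends(word, "ed") && .porter_has_vowel(.porter_chop(word, "ed"))) {
    word <- .porter_chop(word, "ed"); fixup <- TRUE
  } else if (.porter_ends(word, "ing") && .porter_has_vowel(.porter_chop(word, "ing"))) {
    word <- .porter_chop(word, "ing"); fixup <- TRUE
  }
  if (fixup) {
    if (.porter_ends(word, "at") || .porter_ends(word, "bl") || .porter_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_double_cons(word) &&
               !substring(word, nchar(word)) %in% c("l", "s", "z")) {
      word <- substring(word, 1L, nchar(word) - 1L)
    } else if (.porter_measure(word) == 1L && .porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (.porter_ends(word, "y") && .porter_has_vowel(.porter_chop(word, "y"))) {
    word <- paste0(.porter_chop(word, "y"), "i")
  }

  # step 2 (m > 0)
  rules2 <- list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", bli = "ble", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble", logi = "log"
  )
  res <- .porter_step_rules(word, rules2, 0L)
  if (!is.null(res)) word <- res

  # step 3 (m > 0)
  rules3 <- list(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  )
  res <- .porter_step_rules(word, rules3, 0L)
  if (!is.null(res)) word <- res

  # step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  sufs4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
             "ic", "ou")
  # order: longest first so the longest-matching suffix fires
  sufs4 <- sufs4[order(-nchar(sufs4))]
  for (suf in sufs4) {
    if (.porter_ends(word, suf)) {
      stem <- .porter_chop(word, suf)
      ok <- .porter_measure(stem) > 1L
      if (suf == "ion") {
        ok <- ok && substring(stem, nchar(stem)) %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # step 5a
  if (.porter_ends(word, "e")) {
    stem <- .porter_chop(word, "e")
    m <- .porter_measure(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) word <- stem
  }
  # step 5b
  if (.porter_measure(word) > 1L && .porter_double_cons(word) &&
      .porter_ends(word, "l")) {
    word <- substring(word, 1L, nchar(word) - 1L)
  }
  word
}

.stem_cache <- new.env(parent = emptyenv())

#' Porter stemmer
#'
#' Classic Porter (1980) suffix stripping for lowercase English tokens.
#' Tokens of two characters or fewer, and tokens containing non-letters,
#' are returned unchanged.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of stems, same length.
#' @examples
#' porter_stem(c("injured", "injury", "expression"))
#' @export
porter_stem <- function(tokens) {
  vapply(tokens, function(w) {
    hit <- .stem_cache[[w]]
    if (!is.null(hit)) return(hit)
    s <- .porter_stem_one(w)
    assign(w, s, envir = .stem_cache)
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Default stemmer used by the matching layer
#'
#' Porter stemming followed by stripping a single trailing "i". Vanilla
#' Porter maps "injury" to "injuri" but "injured" to "injur"; the trailing-i
#' rule reconciles the two so morphological variants of the same name share a
#' stem. Any function mapping a character vector of tokens to stems can be
#' supplied instead wherever a `stemmer` argument is accepted.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of stems.
#' @examples
#' default_stemmer(c("injured", "injury"))  # both "injur"
#' @export
default_stemmer <- function(tokens) {
  stems <- porter_stem(tokens)
  strip <- nchar(stems) > 2L & endsWith(stems, "i")
  stems[strip] <- substring(stems[strip], 1L, nchar(stems[strip]) - 1L)
  stems
}

#' Built-in English stop-word list
#'
#' A small function-word list used during canonicalization (it drops "by" in
#' phrases like "injured by stun gun"). Replaceable via the `stopwords`
#' argument of [canonicalize()] or a one-word-per-line file.
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "been", "but", "by", "for",
    "from", "had", "has", "have", "in", "into", "is", "it", "its", "no",
    "not", "of", "on", "or", "such", "that", "the", "their", "then",
    "there", "these", "this", "to", "was", "were", "which", "while",
    "with")
}

#' Read a stop-word list from file
#'
#' @param path One lowercase word per line; blank lines ignored.
#' @return Character vector of stop words.
#' @export
read_stopwords <- function(path) {
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  tolower(words[nzchar(words)])
}
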