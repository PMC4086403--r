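# Low-level text segmentation shared by the matching, silver and action layers.
# All offsets in this package are 0-based character offsets, end-exclusive,
# counted in Unicode code points.

#' Tokenize text into alphanumeric tokens with character offsets
#'
#' Tokens are maximal runs of ASCII letters and digits; every other character
#' (including hyphens and slashes) is a separator, so chemical names fragment
#' predictably and matching can operate on whole-token sequences.
#'
#' @param text A single string.
#' @return A data frame with columns `begin`, `end` (0-based, end-exclusive)
#'   and `text`, one row per token, in document order.
#' @examples
#' tokenize_text("Stun gun injury")
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(begin = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z0-9]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(begin = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  begin <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(begin = begin, end = begin + len,
             text = substring(text, begin + 1L, begin + len),
             stringsAsFactors = FALSE)
}

#' Split text into sentences with character offsets
#'
#' A lightweight default splitter: a sentence ends at a run of sentence-final
#' punctuation (`.`, `!`, `?`) followed by whitespace and an upper-case letter
#' or digit. The splitter is deliberately simple and pluggable; callers that
#' have better segmentation (e.g. from an external sentence model) can pass
#' their own spans wherever sentence structure is consumed.
#'
#' @param text A single string.
#' @return A data frame with columns `begin` and `end` (0-based,
#'   end-exclusive), one row per sentence.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(begin = integer(), end = integer(), stringsAsFactors = FALSE))
  }
  # boundary = position right after punctuation+space, before [A-Z0-9]
  m <- gregexpr("[.!?]+[\\s]+(?=[A-Z0-9])", text, perl = TRUE)[[1]]
  starts <- 0L
  if (m[1] != -1L) {
    bnd <- as.integer(m) - 1L + attr(m, "match.length")  # 0-based start of next
    starts <- c(0L, bnd)
  }
  ends <- c(starts[-1], nchar(text))
  df <- data.frame(begin = starts, end = ends, stringsAsFactors = FALSE)
  df[df$end > df$begin, , drop = FALSE]
}

#' Tokenize a document into sentences and tokens
#'
#' @param text A single string.
#' @return A data frame with columns `begin`, `end`, `text` and `sentence`
#'   (1-based sentence index).
#' @export
tokenize_document <- function(text) {
  toks <- tokenize_text(text)
  sents <- split_sentences(text)
  if (nrow(toks) == 0L) {
    toks$sentence <- integer()
    return(toks)
  }
  if (nrow(sents) == 0L) {
    toks$sentence <- rep.int(1L, nrow(toks))
    return(toks)
  }
  toks$sentence <- findInterval(toks$begin, sents$begin)
  toks$sentence[toks$sentence < 1L] <- 1L
  toks
}

# substring by 0-based, end-exclusive offsets
substr0 <- function(text, begin, end) {
  substring(text, begin + 1L, end)
}
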