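test_that("canonicalization reproduces the worked stemming example", {
  a <- canonicalize("injured by stun gun")
  b <- canonicalize("Stun Gun Injury")
  expect_equal(a$tokens, c("gun", "injur", "stun"))
  expect_equal(b$tokens, c("gun", "injur", "stun"))
  expect_equal(overlap_score(a, b), 3L)
})

test_that("canonicalization is idempotent and drops stop words", {
  expect_equal(canonicalize("")$tokens, character(0))
  expect_equal(canonicalize("the of by")$tokens, character(0))
  set.seed(21)
  pool <- c("stun", "gun", "injury", "injured", "leukopenia", "factors",
            "regulatory", "binding", "expression", "by", "of", "the")
  for (i in 1:30) {
    phrase <- paste(sample(pool, sample(1:6, 1), replace = TRUE),
                    collapse = " ")
    once <- canonicalize(phrase)$tokens
    twice <- canonicalize(paste(once, collapse = " "))$tokens
    expect_equal(twice, once)
  }
})

test_that("overlap score is a symmetric multiset intersection", {
  empty <- canonicalize("of the")
  full <- canonicalize("stun gun injury")
  expect_equal(overlap_score(full, full), 3L)
  expect_equal(overlap_score(full, empty), 0L)
  set.seed(8)
  toks <- c("alpha", "beta", "gamma", "delta", "eps")
  for (i in 1:50) {
    a <- canonicalize(paste(sample(toks, sample(0:5, 1), replace = TRUE),
                            collapse = " "))
    b <- canonicalize(paste(sample(toks, sample(0:5, 1), replace = TRUE),
                            collapse = " "))
    expect_equal(overlap_score(a, b), naive_overlap(a$tokens, b$tokens))
    expect_equal(overlap_score(a, b), overlap_score(b, a))
  }
})

test_that("exact matching finds whole-token case-insensitive occurrences", {
  v <- toy_vocab()
  m <- exact_match("Stun gun injury was reported", v)
  expect_equal(nrow(m), 1)
  expect_equal(m$begin, 0L)
  expect_equal(m$end, 15L)
  expect_equal(m$concept_id, "D001")
  expect_equal(m$mode, "exact")
  expect_equal(m$score, 3L)  # token count of the matched name
  # ambiguous names match verbs too: false positives are expected here
  m2 <- exact_match("this may lead to injury", v)
  expect_equal(m2$concept_id, "C001")
  # whole-token only: "leaden" must not match "lead"
  expect_equal(nrow(exact_match("leaden skies", v)), 0)
  expect_equal(nrow(exact_match("", v)), 0)
})

test_that("exact matching agrees with a naive quadratic scan oracle", {
  spec <- fixture_spec(seed = 33, n_docs = 100, distractor_rate = 0.3,
                       variant_rate = 0)
  v <- gen_vocabulary(spec)
  ab <- gen_abstracts(spec, v)
  surfaces <- v$surfaces$surface
  for (doc in ab$documents) {
    got <- exact_match(doc$text, v)
    want <- naive_exact_spans(doc$text, surfaces)
    expect_equal(got$begin, want$begin)
    expect_equal(got$end, want$end)
    # results never overlap
    if (nrow(got) > 1) {
      expect_true(all(got$begin[-1] >= got$end[-nrow(got)]))
    }
  }
})

test_that("approximate matching scores by common tokens above a strict threshold", {
  v <- toy_vocab()
  phr <- data.frame(begin = 0L, end = 19L, text = "injured by stun gun",
                    stringsAsFactors = FALSE)
  m <- approximate_match(phr, v, threshold = 2L)
  expect_equal(nrow(m), 1)
  expect_equal(m$score, 3L)
  expect_equal(m$concept_id, "D001")
  expect_equal(m$mode, "approximate")
  # strict inequality: score 3 is not > 3
  expect_equal(nrow(approximate_match(phr, v, threshold = 3L)), 0)
})

test_that("inflected forms reach their entry through stemming", {
  # leukopenic / leukopenia need a stemmer mapping both to one stem
  stem <- function(tokens) sub("(ia|ic)$", "", tokens)
  df <- data.frame(concept_id = "D002", category = "disease",
                   preferred_name = "leukopenia deficiency",
                   stringsAsFactors = FALSE)
  df$synonyms <- list(character())
  v <- vocabulary(df, stemmer = stem)
  phr <- data.frame(begin = 10L, end = 40L,
                    text = "leukopenic deficiency patients",
                    stringsAsFactors = FALSE)
  m <- approximate_match(phr, v, threshold = 1L)
  expect_equal(nrow(m), 1)
  expect_equal(m$concept_id, "D002")
  # span is the minimal sub-span covering the common tokens
  expect_equal(m$begin, 10L)
  expect_equal(m$end, 31L)  # "leukopenic deficiency"
})

test_that("raising the threshold never adds approximate matches", {
  spec <- fixture_spec(seed = 44, n_docs = 10, variant_rate = 1,
                       distractor_rate = 0)
  v <- gen_vocabulary(spec)
  ab <- gen_abstracts(spec, v)
  for (doc in ab$documents[1:5]) {
    phrases <- candidate_phrases(doc$text)
    prev <- NULL
    for (th in 1:4) {
      m <- approximate_match(phrases, v, threshold = th)
      key <- sprintf("%d-%d-%s", m$begin, m$end, m$concept_id)
      if (!is.null(prev)) expect_true(all(key %in% prev))
      prev <- key
    }
  }
})

test_that("responses normalize to the best entry, direct hits first", {
  v <- toy_vocab()
  expect_equal(normalize_response("stun gun injury", v)$concept_id, "D001")
  expect_equal(normalize_response("IRF4", v)$preferred_name,
               "interferon regulatory factor 4")
  expect_equal(normalize_response("injured by stun gun", v)$concept_id, "D001")
  expect_null(normalize_response("zzz qqq", v))
  # a direct synonym hit beats any approximate score
  df <- data.frame(concept_id = c("A", "B"), category = "disease",
                   preferred_name = c("alpha beta gamma delta", "other name"),
                   stringsAsFactors = FALSE)
  df$synonyms <- list(character(), "alpha beta")
  v2 <- vocabulary(df)
  expect_equal(normalize_response("alpha beta", v2)$concept_id, "B")
})
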