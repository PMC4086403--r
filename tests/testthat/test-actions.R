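toy_lexicon <- function() {
  verb_lexicon(list(inhibit = c("inhibits", "inhibited", "inhibition"),
                    activate = c("activates", "activated"),
                    bind = c("binds", "binding")))
}

test_that("variant uniqueness is enforced and lookups are lemma-keyed", {
  lex <- toy_lexicon()
  expect_equal(unname(lex$variant_index[["inhibits"]]), "inhibit")
  expect_equal(unname(lex$variant_index[["bind"]]), "bind")
  expect_error(verb_lexicon(list(a = "shared", b = "shared")),
               "more than one lemma")
})

test_that("match flags fire on whole tokens; no chemicals means zero weights", {
  lex <- toy_lexicon()
  toks <- tokenize_document("The drug inhibits the target gene strongly.")
  fv <- extract_action_features(toks, lexicon = lex)
  expect_true(fv$match_flags[["inhibit"]])
  expect_false(fv$match_flags[["activate"]])
  expect_true(all(fv$cooc_weights == 0))  # no chemical/gene spans supplied
  expect_error(extract_action_features(toks, lexicon = verb_lexicon(
    structure(list(), names = character()))), "empty")
})

test_that("proximity weights follow 1/(1+d) with max normalization", {
  lex <- toy_lexicon()
  text <- "X inhibits Y"
  toks <- tokenize_document(text)
  chem <- data.frame(begin = 0L, end = 1L)   # X
  gene <- data.frame(begin = 11L, end = 12L) # Y
  fv <- extract_action_features(toks, chem, gene, lex)
  # d = 1 to both neighbours: raw 1/(1+1) = 0.5, sole nonzero -> 1 after norm
  expect_equal(unname(fv$cooc_weights[["inhibit"]]), 1)
  expect_true(all(fv$cooc_weights >= 0 & fv$cooc_weights <= 1))
  # weight zero whenever the flag is off
  expect_true(all(fv$cooc_weights[!fv$match_flags] == 0))
})

test_that("normalized weights are invariant under document duplication", {
  lex <- toy_lexicon()
  text1 <- "X inhibits Y strongly. The complex binds X near Y."
  dup <- paste(text1, text1)
  spans_of <- function(text, word) {
    toks <- tokenize_text(text)
    toks[toks$text == word, c("begin", "end")]
  }
  fv1 <- extract_action_features(tokenize_document(text1),
                                 spans_of(text1, "X"), spans_of(text1, "Y"),
                                 lex)
  fv2 <- extract_action_features(tokenize_document(dup),
                                 spans_of(dup, "X"), spans_of(dup, "Y"), lex)
  expect_equal(fv2$cooc_weights, fv1$cooc_weights, tolerance = 1e-12)
  expect_equal(fv2$match_flags, fv1$match_flags)
})

test_that("match flags do not depend on sentence order", {
  lex <- toy_lexicon()
  a <- "The drug inhibits it. The protein binds it."
  b <- "The protein binds it. The drug inhibits it."
  fa <- extract_action_features(tokenize_document(a), lexicon = lex)
  fb <- extract_action_features(tokenize_document(b), lexicon = lex)
  expect_equal(fa$match_flags, fb$match_flags)
})

# deterministic synthetic multilabel set: label l_i is on iff flag i is on
separable_examples <- function(n, lex, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    flags <- setNames(runif(length(lex$lemmas)) < 0.5, lex$lemmas)
    weights <- setNames(ifelse(flags, round(runif(length(lex$lemmas)), 3), 0),
                        lex$lemmas)
    fv <- structure(list(match_flags = flags, cooc_weights = weights),
                    class = "action_features")
    list(features = fv, labels = lex$lemmas[flags])
  })
}

test_that("one-vs-all training separates a perfectly predictive feature", {
  lex <- toy_lexicon()
  exs <- separable_examples(60, lex, seed = 10)
  scorers <- train_one_vs_all(exs, lex$lemmas, seed = 2)
  micro <- c(tp = 0, fp = 0, fn = 0)
  for (e in exs) {
    got <- decide_labels(e$features, scorers)
    micro["tp"] <- micro["tp"] + length(intersect(got, e$labels))
    micro["fp"] <- micro["fp"] + length(setdiff(got, e$labels))
    micro["fn"] <- micro["fn"] + length(setdiff(e$labels, got))
  }
  f <- 2 * micro["tp"] / (2 * micro["tp"] + micro["fp"] + micro["fn"])
  expect_gte(unname(f), 0.95)
})

test_that("training is deterministic and robust to example order", {
  lex <- toy_lexicon()
  exs <- separable_examples(40, lex, seed = 11)
  s1 <- train_one_vs_all(exs, lex$lemmas, seed = 3)
  s2 <- train_one_vs_all(exs, lex$lemmas, seed = 3)
  expect_identical(s1, s2)
  set.seed(99)
  perm <- sample(length(exs))
  s3 <- train_one_vs_all(exs[perm], lex$lemmas, seed = 3)
  for (e in exs) {
    expect_equal(decide_labels(e$features, s3), decide_labels(e$features, s1))
  }
})

test_that("degenerate training data yields chance scores below threshold", {
  lex <- toy_lexicon()
  fv <- structure(list(
    match_flags = setNames(c(TRUE, FALSE, FALSE), lex$lemmas),
    cooc_weights = setNames(c(0.5, 0, 0), lex$lemmas)),
    class = "action_features")
  # identical positives and negatives for the first label
  exs <- c(replicate(5, list(features = fv, labels = "inhibit"),
                     simplify = FALSE),
           replicate(5, list(features = fv, labels = character()),
                     simplify = FALSE))
  scorers <- train_one_vs_all(exs, "inhibit", seed = 1)
  expect_length(decide_labels(fv, scorers), 0)
  # a label with no positives is disabled with a warning
  expect_warning(s0 <- train_one_vs_all(exs, c("inhibit", "activate"),
                                        seed = 1),
                 "no positive")
  expect_false("activate" %in% decide_labels(fv, s0))
})

test_that("label decisions are multilabel and monotone in the threshold", {
  lex <- toy_lexicon()
  exs <- separable_examples(50, lex, seed = 12)
  scorers <- train_one_vs_all(exs, lex$lemmas, seed = 4)
  fv <- exs[[1]]$features
  sizes <- vapply(c(-5, 0, 5, 50), function(th)
    length(decide_labels(fv, scorers, threshold = th)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 0L)  # all scores below a huge threshold
  multi <- vapply(exs, function(e)
    length(decide_labels(e$features, scorers)), integer(1))
  expect_true(any(multi >= 2))  # several labels can fire at once
  expect_true(any(multi == 0))  # and none may fire
})
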