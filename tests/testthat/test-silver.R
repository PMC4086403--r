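test_that("candidate phrase windows follow the closed-form count", {
  # n-token sentence yields sum_{k=1..6} max(0, n-k+1) windows
  for (n in c(1, 3, 6, 9)) {
    text <- paste(rep("tok", n), collapse = " ")
    got <- nrow(candidate_phrases(text))
    want <- sum(pmax(0, n - seq_len(6) + 1))
    expect_equal(got, want)
  }
  ph <- candidate_phrases("injured by stun gun")
  expect_true("injured by stun gun" %in% ph$text)
  # supplied chunks are returned verbatim
  ch <- candidate_phrases("injured by stun gun",
                          chunks = data.frame(begin = 0L, end = 19L))
  expect_equal(ch$text, "injured by stun gun")
  expect_error(candidate_phrases("ab", chunks = data.frame(begin = 0, end = 9)),
               "chunk")
})

test_that("windows stay within sentence bounds", {
  text <- "Alpha beta. Gamma delta"
  ph <- candidate_phrases(text)
  expect_false(any(grepl("beta. Gamma", ph$text, fixed = TRUE)))
})

test_that("gold filtering drops ambiguous matches absent from the gold list", {
  df <- data.frame(concept_id = c("C010", "C020"), category = "chemical",
                   preferred_name = c("lead", "aspirin compound"),
                   stringsAsFactors = FALSE)
  df$synonyms <- list(character(), character())
  v <- vocabulary(df)
  text <- "high doses lead to aspirin compound accumulation"
  gold <- gold_concept_list("d1", list(chemical = "aspirin compound"))
  sd <- silver_annotate("d1", text, v, gold)
  expect_equal(sd$annotations$concept_id, "C020")  # "lead" filtered out
  # with an all-inclusive gold list filtering is the identity
  gold_all <- gold_concept_list("d1", list(chemical = c("lead", "aspirin compound")))
  sd_all <- silver_annotate("d1", text, v, gold_all)
  expect_equal(sort(sd_all$annotations$concept_id), c("C010", "C020"))
  expect_gte(nrow(sd_all$annotations), nrow(sd$annotations))
  # empty gold list: everything filtered, all labels O
  sd0 <- silver_annotate("d1", text, v, gold_concept_list("d1"))
  expect_equal(nrow(sd0$annotations), 0)
  expect_true(all(unlist(sd0$bio_labels) == "O"))
  # missing gold list: default skip drops everything, keep warns
  sd_skip <- silver_annotate("d1", text, v, NULL)
  expect_equal(nrow(sd_skip$annotations), 0)
  expect_warning(sd_keep <- silver_annotate("d1", text, v, NULL,
                                            missing_gold = "keep"),
                 "unfiltered")
  expect_equal(sort(sd_keep$annotations$concept_id), c("C010", "C020"))
})

test_that("planted exact mentions are fully recovered and nothing maps outside gold", {
  spec <- fixture_spec(seed = 91, n_docs = 30, distractor_rate = 0,
                       variant_rate = 0)
  v <- gen_vocabulary(spec)
  ab <- gen_abstracts(spec, v)
  for (id in names(ab$documents)) {
    sd <- silver_annotate(id, ab$documents[[id]]$text, v, ab$gold[[id]])
    led <- ab$ledger[ab$ledger$doc_id == id, ]
    for (i in seq_len(nrow(led))) {
      expect_true(any(sd$annotations$begin == led$begin[i] &
                        sd$annotations$end == led$end[i] &
                        sd$annotations$concept_id == led$concept_id[i]),
                  label = sprintf("%s span %d-%d recovered", id,
                                  led$begin[i], led$end[i]))
    }
    # post-filter guarantee: every annotation's concept is in the gold list
    for (i in seq_len(nrow(sd$annotations))) {
      norm <- normalize_response(sd$annotations$text[i], v,
                                 categories = sd$annotations$category[i])
      pool <- ab$gold[[id]]$concepts[[sd$annotations$category[i]]]
      expect_true(norm$preferred_name %in% pool)
    }
  }
})

test_that("planted distractors are filtered out; variants need the approximate pass", {
  spec <- fixture_spec(seed = 92, n_docs = 25, distractor_rate = 0.5,
                       variant_rate = 0.6)
  v <- gen_vocabulary(spec)
  ab <- gen_abstracts(spec, v)
  expect_true(all(c("distractor", "variant") %in% ab$ledger$kind))
  n_extra_approx <- 0L
  for (id in names(ab$documents)) {
    sd <- silver_annotate(id, ab$documents[[id]]$text, v, ab$gold[[id]])
    led <- ab$ledger[ab$ledger$doc_id == id, ]
    gold <- ab$gold[[id]]
    dis <- led[led$kind == "distractor", ]
    for (i in seq_len(nrow(dis))) {
      # the distractor concept is not in gold ...
      expect_false(dis$concept_id[i] %in% unlist(gold$concepts) ||
                     any(vapply(gold$concepts, function(p)
                       v$entries$preferred_name[v$entries$concept_id ==
                                                  dis$concept_id[i]] %in% p,
                       TRUE)))
      # ... and no surviving annotation covers its span with that concept
      expect_false(any(sd$annotations$begin == dis$begin[i] &
                         sd$annotations$concept_id == dis$concept_id[i]))
    }
    vr <- led[led$kind == "variant", ]
    for (i in seq_len(nrow(vr))) {
      hit <- sd$annotations$begin == vr$begin[i] & sd$annotations$end == vr$end[i]
      expect_true(any(hit))
      if (any(sd$annotations$mode[hit] == "approximate")) {
        n_extra_approx <- n_extra_approx + 1L
      }
    }
    # variant_rate > 0 only inflects diseases; without the approximate pass
    # those spans are lost
    sd_noapprox <- silver_annotate(id, ab$documents[[id]]$text, v,
                                   ab$gold[[id]], approx_categories = character())
    for (i in seq_len(nrow(vr))) {
      expect_false(any(sd_noapprox$annotations$begin == vr$begin[i] &
                         sd_noapprox$annotations$end == vr$end[i]))
    }
  }
  expect_gt(n_extra_approx, 0)
})

test_that("BIO emission round-trips spans and separates sentences", {
  spec <- fixture_spec(seed = 93, n_docs = 15, distractor_rate = 0.2,
                       variant_rate = 0.3)
  v <- gen_vocabulary(spec)
  ab <- gen_abstracts(spec, v)
  for (id in names(ab$documents)) {
    sd <- silver_annotate(id, ab$documents[[id]]$text, v, ab$gold[[id]])
    for (category in names(sd$bio_labels)) {
      lines <- emit_bio(sd, category)
      expect_equal(sum(!nzchar(lines)),
                   length(unique(sd$tokens$sentence)) - 1L)
      decoded <- decode_bio(lines)
      ann <- sd$annotations[sd$annotations$category == category, , drop = FALSE]
      expect_equal(nrow(decoded), nrow(ann))
      if (nrow(ann)) {
        # decoded spans snap to token boundaries of the original spans
        for (i in seq_len(nrow(ann))) {
          expect_true(any(decoded$begin <= ann$begin[i] &
                            decoded$end >= ann$end[i] - 0L |
                            (decoded$begin >= ann$begin[i] &
                               decoded$end <= ann$end[i])))
        }
      }
      # label structure: no I without a preceding B/I
      labels <- sd$bio_labels[[category]]
      if (length(labels) > 1) {
        bad <- which(labels[-1] == "I" & labels[-length(labels)] == "O") + 1L
        expect_length(bad, 0)
      }
    }
  }
  expect_equal(decode_bio(character()), data.frame(begin = integer(),
                                                   end = integer()))
})

test_that("surviving responses collapse to unique preferred names per category", {
  df <- data.frame(concept_id = c("C1", "D1"),
                   category = c("chemical", "disease"),
                   preferred_name = c("aspirin compound", "stun gun injury"),
                   stringsAsFactors = FALSE)
  df$synonyms <- list("acetylsalicylic acid", character())
  v <- vocabulary(df)
  ann <- data.frame(
    begin = c(0L, 20L, 40L, 60L),
    end = c(10L, 30L, 50L, 70L),
    text = c("aspirin compound", "Acetylsalicylic Acid", "stun gun injury",
             "zzz qqq www"),
    concept_id = c("C1", "C1", "D1", "D1"),
    category = c("chemical", "chemical", "disease", "disease"),
    score = 1L, mode = "exact", stringsAsFactors = FALSE)
  cp <- responses_to_concepts("d1", ann, v)
  expect_equal(cp$concepts$chemical, "aspirin compound")  # two mentions, one concept
  expect_equal(cp$concepts$disease, "stun gun injury")    # garbage span omitted
})
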