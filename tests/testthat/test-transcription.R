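table2_doc <- function() {
  # document laid out so the printed offsets hold: entity at 19-49,
  # trigger "expression" at 55-65
  txt <- paste0(strrep("x", 19), "interferon regulatory factor 4",
                " xxxx ", "expression", " tail tail2 tail3")
  ann <- paste(
    "T1\tProtein 19 49\tinterferon regulatory factor 4",
    "T2\tProtein 60 64\tssio",
    "T3\tProtein 66 70\ttail",
    "T4\tProtein 71 76\ttail2",
    "T5\tProtein 77 82\ttail3",
    "T13\tProtein 55 59\texpr",
    "T11\tGene_expression 55 65\texpression",
    "E2\tGene_expression:T11 Theme:T1",
    "M1\tSpeculation E2",
    "*\tEquiv T2 T3",
    "R1\tCoreference Subject:T13 Object:T3",
    "R2\tCoreference Subject:T13 Object:T4",
    "R3\tCoreference Subject:T13 Object:T5",
    sep = "\n")
  read_standoff(txt, ann, doc_id = "table2")
}

test_that("type URIs are the uima:ts: scheme plus the qualified name", {
  expect_equal(make_type_uri("uima.tcas.Annotation"),
               "uima:ts:uima.tcas.Annotation")
  expect_equal(make_type_uri("a"), "uima:ts:a")
  expect_error(make_type_uri(""), "non-empty")
  set.seed(4)
  for (i in 1:25) {
    qn <- paste(sample(letters, sample(2:8, 1), replace = TRUE), collapse = ".")
    uri <- make_type_uri(qn)
    expect_true(startsWith(uri, "uima:ts:"))
    expect_true(endsWith(uri, qn))
  }
})

test_that("entities transcribe with id, typed infons and length = end - begin", {
  bd <- bionlp_to_bioc(table2_doc())
  anns <- bd$passages[[1]]$annotations
  ids <- vapply(anns, `[[`, "", "id")
  a1 <- anns[[which(ids == "T1")]]
  expect_equal(unname(a1$infons["type"]), "Entity")
  expect_equal(unname(a1$infons["category"]), "Protein")
  expect_match(unname(a1$infons["typeUri"]), "^uima:ts:")
  expect_equal(a1$locations[[1]]$offset, 19L)
  expect_equal(a1$locations[[1]]$length, 30L)
  expect_equal(a1$text, "interferon regulatory factor 4")
})

test_that("events become relations with trigger node, roles and modification flags", {
  bd <- bionlp_to_bioc(table2_doc())
  anns <- bd$passages[[1]]$annotations
  rels <- bd$passages[[1]]$relations
  ids <- vapply(anns, `[[`, "", "id")
  trig <- anns[[which(ids == "TRIGGER_55_65")]]
  expect_equal(unname(trig$infons["type"]), "Trigger")
  expect_false("category" %in% names(trig$infons))
  expect_equal(trig$locations[[1]]$offset, 55L)
  expect_equal(trig$locations[[1]]$length, 10L)

  rids <- vapply(rels, `[[`, "", "id")
  e2 <- rels[[which(rids == "E2")]]
  expect_equal(unname(e2$infons["type"]), "Event")
  expect_equal(unname(e2$infons["category"]), "Gene_expression")
  expect_equal(unname(e2$infons["negation"]), "false")
  expect_equal(unname(e2$infons["speculation"]), "true")
  expect_equal(e2$nodes[[1]]$refid, "TRIGGER_55_65")
  expect_equal(e2$nodes[[1]]$role, "EventTrigger")
  expect_equal(e2$nodes[[2]]$refid, "T1")
  expect_equal(e2$nodes[[2]]$role, "Theme")
})

test_that("equivalences get empty-role nodes; subject-sharing corefs merge", {
  bd <- bionlp_to_bioc(table2_doc())
  rels <- bd$passages[[1]]$relations
  rids <- vapply(rels, `[[`, "", "id")
  eq <- rels[[grep("^EE", rids)]]
  expect_equal(unname(eq$infons["type"]), "Equivalent")
  expect_equal(vapply(eq$nodes, `[[`, "", "refid"), c("T2", "T3"))
  expect_equal(vapply(eq$nodes, `[[`, "", "role"), c("", ""))

  rt <- rels[[which(rids == "RT13")]]
  expect_equal(unname(rt$infons["type"]), "Coreference")
  expect_length(rt$nodes, 4)  # 1 Subject + 3 Objects
  expect_equal(vapply(rt$nodes, `[[`, "", "role"),
               c("Subject", "Object", "Object", "Object"))
  expect_equal(rt$nodes[[1]]$refid, "T13")
  expect_equal(vapply(rt$nodes[-1], `[[`, "", "refid"), c("T3", "T4", "T5"))
})

test_that("the inverse transcription recovers the standoff lines", {
  back <- bioc_to_bionlp(bionlp_to_bioc(table2_doc()))
  out <- write_standoff(back)
  lines <- strsplit(out$ann, "\n")[[1]]
  # trigger re-issued a fresh T id with category from the event
  expect_equal(sum(grepl("\tGene_expression 55 65\texpression", lines)), 1)
  expect_equal(sum(grepl("^E2\tGene_expression:T[0-9]+ Theme:T1$", lines)), 1)
  expect_true("M1\tSpeculation E2" %in% lines)
  expect_true("*\tEquiv T2 T3" %in% lines)
  expect_equal(sum(grepl("Coreference Subject:T13", lines)), 3)
})

test_that("a document with only entities has an empty a2", {
  txt <- "alpha beta"
  doc <- read_standoff(txt, "T1\tProtein 0 5\talpha")
  back <- bioc_to_bionlp(bionlp_to_bioc(doc))
  expect_equal(write_standoff(back)$a2, "")
})

test_that("every produced element carries exactly one type and typeUri infon", {
  docs <- gen_standoff(fixture_spec(seed = 404, n_docs = 15))
  for (doc in docs) {
    bd <- bionlp_to_bioc(doc)
    elems <- c(bioconc:::.doc_annotations(bd), bioconc:::.doc_relations(bd))
    for (el in elems) {
      expect_equal(sum(names(el$infons) == "type"), 1)
      expect_equal(sum(names(el$infons) == "typeUri"), 1)
    }
  }
})

test_that("transcription conserves counts and modification flags", {
  docs <- gen_standoff(fixture_spec(seed = 505, n_docs = 20))
  for (doc in docs) {
    bd <- bionlp_to_bioc(doc)
    rels <- bioconc:::.doc_relations(bd)
    types <- vapply(rels, function(r) unname(r$infons["type"]), "")
    expect_equal(sum(types == "Event"), length(doc$events))
    expect_equal(sum(types == "Equivalent"), length(doc$equivalences))
    subj <- unique(vapply(doc$coreferences, `[[`, "", "subject"))
    expect_equal(sum(types == "Coreference"), length(subj))
    for (r in rels[types == "Event"]) {
      ev_id <- r$id
      kinds <- vapply(doc$modifications[vapply(doc$modifications,
                                               function(m) m$target == ev_id,
                                               TRUE)],
                      function(m) m$kind, "")
      expect_equal(unname(r$infons["negation"]),
                   tolower(as.character("Negation" %in% kinds)))
      expect_equal(unname(r$infons["speculation"]),
                   tolower(as.character("Speculation" %in% kinds)))
    }
  }
})

test_that("coreference chains of length k merge into k+1 node relations", {
  docs <- gen_standoff(fixture_spec(seed = 606, n_docs = 25))
  for (doc in docs) {
    if (!length(doc$coreferences)) next
    bd <- bionlp_to_bioc(doc)
    rels <- bioconc:::.doc_relations(bd)
    types <- vapply(rels, function(r) unname(r$infons["type"]), "")
    subjects <- vapply(doc$coreferences, `[[`, "", "subject")
    for (subj in unique(subjects)) {
      k <- sum(subjects == subj)
      rel <- rels[types == "Coreference" &
                    vapply(rels, `[[`, "", "id") == paste0("R", subj)]
      expect_length(rel, 1)
      expect_length(rel[[1]]$nodes, k + 1)
    }
  }
})

test_that("round trip through BioC is the identity modulo regenerated ids", {
  docs <- gen_standoff(fixture_spec(seed = 707, n_docs = 40))
  for (doc in docs) {
    back <- bioc_to_bionlp(bionlp_to_bioc(doc))
    expect_identical(canonical_standoff(back), canonical_standoff(doc))
  }
})

test_that("an Event relation without an EventTrigger node is a structural error", {
  doc <- bioc_document("d", passages = list(bioc_passage(
    0, text = "abc def",
    annotations = list(bioc_annotation("T1", c(typeUri = "u", type = "Entity",
                                               category = "Protein"),
                                       list(bioc_location(0, 3)), "abc")),
    relations = list(bioc_relation("E1",
                                   c(typeUri = "u", type = "Event",
                                     category = "Binding",
                                     negation = "false", speculation = "false"),
                                   list(bioc_node("T1", "Theme")))))))
  expect_error(bioc_to_bionlp(doc), "EventTrigger")
})
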