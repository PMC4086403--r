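# Seeded synthetic-corpus generation. Every generator is a pure function of
# (spec, seed): the RNG state is saved and restored around each call, and a
# fixed seed reproduces the output byte for byte. Concept-name tokens and
# filler tokens are drawn from disjoint syllable alphabets so that a planted
# mention is the only place its surface form can occur, which makes ledgers
# exact: downstream recall/precision claims can be checked span by span.

#' Fixture generation parameters
#'
#' @param seed Integer seed; all generators derive their randomness from it.
#' @param n_docs Number of documents to generate.
#' @param vocab_size Named integer vector: entries per category.
#' @param synonym_rate Probability that an entry carries a synonym.
#' @param variant_rate Probability that a planted disease mention is an
#'   inflected morphological variant (recoverable only by approximate
#'   matching).
#' @param distractor_rate Probability of planting an ambiguous mention of a
#'   concept absent from the document's gold list (a false positive the
#'   silver filter must remove).
#' @param event_density Mean number of events per standoff document.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_docs = 20L,
                         vocab_size = c(chemical = 8L, gene = 8L,
                                        disease = 8L, action = 4L),
                         synonym_rate = 0.5, variant_rate = 0.3,
                         distractor_rate = 0.2, event_density = 2) {
  rates <- c(synonym_rate, variant_rate, distractor_rate)
  stopifnot(all(rates >= 0 & rates <= 1), n_docs >= 0L,
            all(vocab_size >= 0L), event_density >= 0)
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 vocab_size = vocab_size, synonym_rate = synonym_rate,
                 variant_rate = variant_rate,
                 distractor_rate = distractor_rate,
                 event_density = event_density),
            class = "fixture_spec")
}

# run expr under a local RNG seeded with `seed`, restoring global state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# three-syllable concept words (vowel-final, Porter-friendly) vs
# consonant-final two-syllable filler words: disjoint by construction
.concept_syllables <- c("ba", "do", "mi", "ra", "ke", "lu", "zo", "ti",
                        "pa", "ne", "su", "ga")
.filler_syllables <- c("vex", "gorp", "snib", "trul", "dran", "plof",
                       "quem", "wisk", "jolt", "fyn")

.gen_word <- function(syllables, n_syl) {
  paste(sample(syllables, n_syl, replace = TRUE), collapse = "")
}

.gen_word_pool <- function(n, syllables, n_syl) {
  pool <- character()
  while (length(pool) < n) {
    pool <- unique(c(pool, replicate(n, .gen_word(syllables, n_syl))))
  }
  pool[seq_len(n)]
}

.inflect <- function(word) {
  paste0(word, sample(c("s", "ed", "ic", "ing"), 1L))
}

#' Generate a synthetic vocabulary
#'
#' Multi-token concept names (2-3 tokens) with token sets disjoint across
#' entries; with probability `synonym_rate` an entry carries a synonym that
#' is a token permutation or a one-token replacement of the preferred name,
#' so every synonym canonicalizes to a form overlapping its preferred name.
#'
#' @param spec A [fixture_spec()].
#' @return A [vocabulary()].
#' @export
gen_vocabulary <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    n_entries <- sum(spec$vocab_size)
    if (n_entries == 0L) {
      return(vocabulary(data.frame(concept_id = character(),
                                   category = character(),
                                   preferred_name = character(),
                                   stringsAsFactors = FALSE)))
    }
    n_tok <- sample(2:3, n_entries, replace = TRUE)
    words <- .gen_word_pool(sum(n_tok) + n_entries, .concept_syllables, 3L)
    extra <- words[seq_len(n_entries)]            # replacement tokens
    words <- words[-seq_len(n_entries)]
    categories <- rep(names(spec$vocab_size), spec$vocab_size)
    offset <- 0L
    entries <- lapply(seq_len(n_entries), function(i) {
      toks <- words[offset + seq_len(n_tok[i])]
      offset <<- offset + n_tok[i]
      name <- paste(toks, collapse = " ")
      syn <- character()
      if (runif(1) < spec$synonym_rate) {
        syn <- if (runif(1) < 0.5 && length(toks) > 1L) {
          paste(rev(toks), collapse = " ")        # permutation
        } else {
          paste(c(toks[-length(toks)], extra[i]), collapse = " ")
        }
        if (identical(syn, name)) syn <- character()
      }
      list(concept_id = sprintf("%s%03d", toupper(substr(categories[i], 1, 1)), i),
           category = categories[i], preferred_name = name, synonyms = syn)
    })
    df <- data.frame(
      concept_id = vapply(entries, `[[`, "", "concept_id"),
      category = vapply(entries, `[[`, "", "category"),
      preferred_name = vapply(entries, `[[`, "", "preferred_name"),
      stringsAsFactors = FALSE)
    df$synonyms <- lapply(entries, `[[`, "synonyms")
    vocabulary(df)
  })
}

.cap <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Generate synthetic abstracts with planted mentions
#'
#' Each document is a handful of filler-word sentences with concept mentions
#' planted between fillers. A planted mention is the exact surface of a
#' vocabulary name or synonym; disease mentions are, with probability
#' `variant_rate`, inflected variants of the name's head token (only the
#' approximate matcher can recover those). With probability
#' `distractor_rate`, an additional mention of a concept deliberately absent
#' from the document's gold list is planted. The ledger records the ground
#' truth for every planted span.
#'
#' @param spec A [fixture_spec()].
#' @param vocab A [vocabulary()], typically from [gen_vocabulary()].
#' @return A list with `documents` (named list of `list(doc_id, text)`),
#'   `gold` (named list of [gold_concept_list()]), and `ledger` (data frame
#'   with columns `doc_id`, `begin`, `end`, `surface`, `concept_id`,
#'   `category`, `kind` in `exact`/`variant`/`distractor`).
#' @export
gen_abstracts <- function(spec, vocab) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(vocab, "vocabulary"))
  .with_seed(spec$seed + 1L, {
    docs <- list(); gold <- list()
    ledger <- list()
    n_entries <- nrow(vocab$entries)
    fillers <- .gen_word_pool(40L, .filler_syllables, 2L)
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc%03d", d)
      n_ment <- if (n_entries) min(sample(3:6, 1L), n_entries) else 0L
      # without replacement: one plant per concept per document, so a
      # distractor can never coincide with a gold concept of the same doc
      picks <- if (n_ment) sample(n_entries, n_ment) else integer()
      plants <- lapply(picks, function(ei) {
        e <- vocab$entries[ei, ]
        surfaces <- c(e$preferred_name, e$synonyms[[1]])
        surface <- sample(surfaces, 1L)
        kind <- "exact"
        if (runif(1) < spec$distractor_rate) {
          kind <- "distractor"
        } else if (e$category == "disease" && runif(1) < spec$variant_rate) {
          toks <- strsplit(surface, " ", fixed = TRUE)[[1]]
          toks[length(toks)] <- .inflect(toks[length(toks)])
          surface <- paste(toks, collapse = " ")
          kind <- "variant"
        }
        list(entry = ei, surface = surface, kind = kind)
      })
      # assemble sentences: each sentence = fillers with at most one plant
      pieces <- character(); cursor <- 0L
      text <- ""
      append_piece <- function(piece, sep) {
        if (nzchar(text)) {
          text <<- paste0(text, sep)
          cursor <<- cursor + nchar(sep)
        }
        b <- cursor
        text <<- paste0(text, piece)
        cursor <<- cursor + nchar(piece)
        c(b, cursor)
      }
      n_sent <- max(2L, length(plants))
      plant_sent <- if (length(plants)) {
        sample(rep_len(seq_len(n_sent), length(plants)))
      } else integer()
      for (s in seq_len(n_sent)) {
        sent_fill <- sample(fillers, sample(4:7, 1L), replace = TRUE)
        sent_fill[1] <- .cap(sent_fill[1])
        sep <- if (s == 1L) "" else " "
        append_piece(paste(sent_fill[1:2], collapse = " "), sep)
        for (pi in which(plant_sent == s)) {
          span <- append_piece(plants[[pi]]$surface, " ")
          ledger[[length(ledger) + 1L]] <- data.frame(
            doc_id = doc_id, begin = span[1], end = span[2],
            surface = plants[[pi]]$surface,
            concept_id = vocab$entries$concept_id[plants[[pi]]$entry],
            category = vocab$entries$category[plants[[pi]]$entry],
            kind = plants[[pi]]$kind, stringsAsFactors = FALSE)
        }
        append_piece(paste(sent_fill[-(1:2)], collapse = " "), " ")
        append_piece(".", "")
      }
      docs[[doc_id]] <- list(doc_id = doc_id, text = text)
      concepts <- list()
      for (p in plants) {
        if (p$kind == "distractor") next
        e <- vocab$entries[p$entry, ]
        concepts[[e$category]] <- unique(c(concepts[[e$category]],
                                           e$preferred_name))
      }
      gold[[doc_id]] <- gold_concept_list(doc_id, concepts)
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger) else data.frame(
      doc_id = character(), begin = integer(), end = integer(),
      surface = character(), concept_id = character(), category = character(),
      kind = character(), stringsAsFactors = FALSE)
    list(documents = docs, gold = gold, ledger = ledger)
  })
}

#' Generate synthetic standoff documents
#'
#' Filler-sentence texts with entity annotations over random tokens, events
#' (with nesting, modifications), equivalence groups and coreference chains
#' that share a subject (a chain of length k yields, after transcription, a
#' merged BioC relation with k+1 nodes).
#'
#' @param spec A [fixture_spec()].
#' @return Named list of [standoff_document()] objects.
#' @export
gen_standoff <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed + 2L, {
    fillers <- .gen_word_pool(40L, .filler_syllables, 2L)
    ent_cats <- c("Protein", "Gene", "Chemical")
    ev_cats <- c("Gene_expression", "Binding", "Regulation", "Phosphorylation")
    docs <- list()
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("std%03d", d)
      words <- sample(fillers, sample(30:45, 1L), replace = TRUE)
      text <- paste(words, collapse = " ")
      toks <- tokenize_text(text)
      n_tok <- nrow(toks)
      n_ent <- sample(3:6, 1L)
      n_ev <- stats::rpois(1L, spec$event_density)
      avail <- sample(n_tok)  # token indices to allocate, no reuse
      need <- n_ent + n_ev
      avail <- avail[seq_len(min(need, n_tok))]
      ent_idx <- avail[seq_len(min(n_ent, length(avail)))]
      trig_idx <- setdiff(avail, ent_idx)
      n_ev <- length(trig_idx)
      tbs <- list(); tid <- 0L
      mk_tb <- function(tok_i, category) {
        tid <<- tid + 1L
        tb <- text_bound(sprintf("T%d", tid), category, toks$begin[tok_i],
                         toks$end[tok_i], toks$text[tok_i])
        tbs[[length(tbs) + 1L]] <<- tb
        tb$id
      }
      ent_ids <- vapply(ent_idx, function(i)
        mk_tb(i, sample(ent_cats, 1L)), character(1))
      evs <- list(); mods <- list(); n_mod <- 0L
      ev_ids <- character()
      for (k in seq_len(n_ev)) {
        trig_id <- mk_tb(trig_idx[k], category <- sample(ev_cats, 1L))
        theme <- sample(ent_ids, 1L)
        args <- data.frame(role = "Theme", target = theme,
                           stringsAsFactors = FALSE)
        # nest: reference an earlier event as Cause sometimes
        if (length(ev_ids) && runif(1) < 0.3) {
          args <- rbind(args, data.frame(role = "Cause",
                                         target = sample(ev_ids, 1L),
                                         stringsAsFactors = FALSE))
        } else if (length(ent_ids) > 1L && runif(1) < 0.3) {
          cause <- sample(setdiff(ent_ids, theme), 1L)
          args <- rbind(args, data.frame(role = "Cause", target = cause,
                                         stringsAsFactors = FALSE))
        }
        ev_id <- sprintf("E%d", k)
        evs[[k]] <- standoff_event(ev_id, category, trig_id, args)
        ev_ids <- c(ev_ids, ev_id)
        for (kind in c("Negation", "Speculation")) {
          if (runif(1) < 0.2) {
            n_mod <- n_mod + 1L
            mods[[n_mod]] <- standoff_modification(sprintf("M%d", n_mod),
                                                   kind, ev_id)
          }
        }
      }
      eqs <- list()
      pool <- ent_ids
      if (length(pool) >= 2L && runif(1) < 0.6) {
        g <- sample(pool, sample(2:min(3L, length(pool)), 1L))
        eqs[[1]] <- equiv_group(g)
        pool <- setdiff(pool, g)
      }
      crs <- list()
      if (length(ent_ids) >= 3L && runif(1) < 0.6) {
        subj <- sample(ent_ids, 1L)
        objs <- sample(setdiff(ent_ids, subj),
                       sample(1:min(3L, length(ent_ids) - 1L), 1L))
        for (oi in seq_along(objs)) {
          crs[[oi]] <- coref_link(sprintf("R%d", oi), subj, objs[oi])
        }
      }
      docs[[doc_id]] <- standoff_document(doc_id, text, tbs, evs, mods,
                                          eqs, crs)
    }
    docs
  })
}

#' Write a full fixture set to a directory
#'
#' Emits the vocabulary TSV, the gold-list TSV, one `.txt`/`.a1`/`.a2`
#' triple per standoff document, one `.txt` per abstract, and the planted
#' -span ledger as TSV.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_fixture_set <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vocab <- gen_vocabulary(spec)
  write_vocabulary(vocab, file.path(dir, "vocabulary.tsv"))
  abs_ <- gen_abstracts(spec, vocab)
  for (doc in abs_$documents) {
    .write_file(doc$text, file.path(dir, paste0(doc$doc_id, ".txt")))
  }
  write_gold_lists(abs_$gold, file.path(dir, "gold.tsv"))
  led <- abs_$ledger
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s", led$doc_id, led$begin,
                   led$end, led$surface, led$concept_id, led$category,
                   led$kind)
  .write_file(paste0(paste(c("doc_id\tbegin\tend\tsurface\tconcept_id\tcategory\tkind",
                             lines), collapse = "\n"), "\n"),
              file.path(dir, "ledger.tsv"))
  write_standoff_dir(gen_standoff(spec), dir)
  invisible(dir)
}
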