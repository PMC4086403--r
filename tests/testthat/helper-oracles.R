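# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (brute force / enumeration) kept free of the code paths it
# checks.

# ---- structural canonical form of a standoff document ----------------------
# Compares documents modulo regenerated trigger / coreference / equivalence
# ids: entities, recursively resolved event structures, equivalence groups
# and coreference pairs are serialized to sorted strings.

entity_key <- function(tb) sprintf("%s@%d-%d:%s", tb$category, tb$begin, tb$end, tb$text)

canonical_standoff <- function(doc) {
  trig_ids <- unique(vapply(doc$events, function(e) e$trigger, ""))
  ev_key <- function(eid, seen = character()) {
    if (eid %in% seen) return("CYCLE")
    ev <- doc$events[[eid]]
    trig <- doc$text_bounds[[ev$trigger]]
    kinds <- sort(vapply(
      doc$modifications[vapply(doc$modifications, function(m) m$target == eid, TRUE)],
      function(m) m$kind, ""))
    args <- character()
    if (nrow(ev$args)) {
      args <- vapply(seq_len(nrow(ev$args)), function(i) {
        tg <- ev$args$target[i]
        tgt <- if (startsWith(tg, "E")) {
          ev_key(tg, c(seen, eid))
        } else entity_key(doc$text_bounds[[tg]])
        paste0(ev$args$role[i], "=", tgt)
      }, "")
    }
    sprintf("%s[%d-%d]{%s}(%s)", ev$category, trig$begin, trig$end,
            paste(kinds, collapse = ","), paste(sort(args), collapse = ";"))
  }
  ents <- vapply(doc$text_bounds[!names(doc$text_bounds) %in% trig_ids],
                 entity_key, "")
  list(
    text = doc$text,
    entities = sort(unname(ents)),
    events = sort(vapply(names(doc$events), ev_key, "")),
    equivalences = sort(vapply(doc$equivalences, function(g)
      paste(sort(vapply(g$members, function(m)
        entity_key(doc$text_bounds[[m]]), "")), collapse = "|"), "")),
    coreferences = sort(vapply(doc$coreferences, function(r)
      paste(entity_key(doc$text_bounds[[r$subject]]),
            entity_key(doc$text_bounds[[r$object]]), sep = ">"), ""))
  )
}

# ---- naive quadratic exact-match oracle ------------------------------------
# Enumerates every token window equal to a surface form, then applies
# leftmost-longest greedy selection; returns begin/end spans.

naive_exact_spans <- function(text, surfaces) {
  toks <- tokenize_text(text)
  low <- tolower(toks$text)
  surf_toks <- lapply(surfaces, function(s) tokenize_text(tolower(s))$text)
  surf_toks <- surf_toks[lengths(surf_toks) > 0]
  hits <- list()
  for (i in seq_len(nrow(toks))) {
    for (st in surf_toks) {
      j <- i + length(st) - 1L
      if (j <= nrow(toks) && identical(low[i:j], st)) {
        hits[[length(hits) + 1L]] <- c(toks$begin[i], toks$end[j], length(st))
      }
    }
  }
  if (!length(hits)) return(data.frame(begin = integer(), end = integer()))
  h <- do.call(rbind, hits)
  h <- h[order(h[, 1], -h[, 3]), , drop = FALSE]
  keep <- list(); last_end <- -1L
  for (r in seq_len(nrow(h))) {
    if (h[r, 1] >= last_end) {
      keep[[length(keep) + 1L]] <- h[r, 1:2]
      last_end <- h[r, 2]
    }
  }
  k <- do.call(rbind, keep)
  data.frame(begin = k[, 1], end = k[, 2])
}

# ---- quadratic multiset-intersection oracle --------------------------------

naive_overlap <- function(a, b) {
  used <- rep(FALSE, length(b))
  n <- 0L
  for (x in a) {
    for (j in seq_along(b)) {
      if (!used[j] && b[j] == x) {
        used[j] <- TRUE; n <- n + 1L; break
      }
    }
  }
  n
}

# ---- brute-force micro-averaged P/R/F counter ------------------------------
# Independent of micro_prf: per doc and category, maps names through a flat
# synonym table by case-insensitive equality, then counts pairs.

naive_micro_prf <- function(gold, pred, surface_table) {
  # surface_table: data.frame(surface, preferred, category)
  map1 <- function(x, category) {
    hit <- which(tolower(surface_table$surface) == tolower(x) &
                   surface_table$category == category)
    if (length(hit)) surface_table$preferred[hit[1]] else paste0("?", tolower(x))
  }
  cats <- unique(unlist(lapply(gold, function(g) names(g$concepts))))
  out <- list()
  for (category in cats) {
    tp <- fp <- fn <- 0L
    for (g in gold) {
      p <- NULL
      for (q in pred) if (q$doc_id == g$doc_id) p <- q
      gset <- unique(vapply(g$concepts[[category]] %||% character(), map1, "",
                            category = category))
      pset <- unique(vapply((if (is.null(p)) character() else
        p$concepts[[category]]) %||% character(), map1, "", category = category))
      for (x in pset) if (x %in% gset) tp <- tp + 1L else fp <- fp + 1L
      for (x in gset) if (!x %in% pset) fn <- fn + 1L
    }
    prec <- if (tp + fp) 100 * tp / (tp + fp) else 0
    rec <- if (tp + fn) 100 * tp / (tp + fn) else 0
    f <- if (prec + rec) 2 * prec * rec / (prec + rec) else 0
    out[[category]] <- c(tp = tp, fp = fp, fn = fn, precision = prec,
                         recall = rec, f_score = f)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random gold/prediction sets over a tiny vocabulary, for the eval oracle
random_eval_case <- function(n_docs, vocab_df, seed) {
  set.seed(seed)
  cats <- unique(vocab_df$category)
  gold <- list(); pred <- list()
  for (d in seq_len(n_docs)) {
    id <- sprintf("d%03d", d)
    gc <- list(); pc <- list()
    for (category in cats) {
      pool <- vocab_df$preferred_name[vocab_df$category == category]
      gc[[category]] <- sample(pool, sample(0:min(4, length(pool)), 1))
      # predictions: a mix of correct names, synonyms, case noise, garbage
      ppicks <- sample(pool, sample(0:min(4, length(pool)), 1))
      noisy <- vapply(ppicks, function(x)
        if (runif(1) < 0.3) toupper(x) else x, "")
      if (runif(1) < 0.3) noisy <- c(noisy, paste0("junk", sample(99, 1)))
      pc[[category]] <- unname(noisy)
    }
    gold[[d]] <- gold_concept_list(id, gc)
    pred[[d]] <- concept_prediction(id, pc)
  }
  list(gold = gold, pred = pred)
}

# nine-entry vocabulary shared by the evaluation tests
eval_vocab_df <- function() {
  df <- data.frame(
    concept_id = sprintf("K%02d", 1:9),
    category = rep(c("chemical", "gene", "disease"), each = 3),
    preferred_name = c("alpha acid", "beta oxide", "gamma salt",
                       "delta kinase", "epsilon factor", "zeta receptor",
                       "eta fever", "theta pox", "iota plague"),
    stringsAsFactors = FALSE)
  df$synonyms <- list("first acid", character(), "salt of gamma",
                      character(), "e factor", character(),
                      "fever of eta", character(), character())
  df
}

flat_surface_table <- function(df) {
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(surface = c(df$preferred_name[i], df$synonyms[[i]]),
               preferred = df$preferred_name[i],
               category = df$category[i], stringsAsFactors = FALSE)
  }))
}

# small hand-rolled vocabulary shared by matching tests
toy_vocab <- function() {
  df <- data.frame(
    concept_id = c("D001", "D002", "C001", "G001"),
    category = c("disease", "disease", "chemical", "gene"),
    preferred_name = c("Stun Gun Injury", "leukopenia", "lead", "interferon regulatory factor 4"),
    stringsAsFactors = FALSE)
  df$synonyms <- list(character(), "white blood cell deficiency", "plumbum", "IRF4")
  vocabulary(df)
}
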