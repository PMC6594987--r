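# Shared fixtures: small seeded corpora and evaluation helpers.

TABLE_SENT <- paste("Abstract: Whole-cell voltage recordings were made in vivo",
                    "in the ventral posterior medial nucleus (VPM)")

make_corpus <- function(seed = 7, docs = 10, sents = 8, ...) {
  generate_corpus(generator_config(seed = seed, n_documents = docs,
                                   sentences_per_document = sents, ...))
}

# span-level F1 of predicted BIO sequences against gold BIO sequences
span_f1 <- function(sents, preds, entity_type, mode = "strict") {
  tp <- fp <- fn <- 0L
  for (i in seq_along(sents)) {
    s <- sents[[i]]
    toks <- data.frame(surface = s$Word, begin = s$Begin, end = s$End,
                       stringsAsFactors = FALSE)
    ps <- suppressWarnings(bio_to_spans(toks, preds[[i]], entity_type))
    gs <- suppressWarnings(bio_to_spans(toks, s$GoldLabel, entity_type))
    r <- prf(ps, gs, mode)
    tp <- tp + r$tp; fp <- fp + r$fp; fn <- fn + r$fn
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# train a quick CRF on a generated corpus and return model + splits
quick_crf <- function(entity_type = "BrainRegion", seed = 7, docs = 10,
                      sents = 8, split_seed = 2, maxit = 80) {
  corpus <- make_corpus(seed = seed, docs = docs, sents = sents)
  feats <- corpus_sentences(corpus, entity_type)
  sp <- split_corpus(length(feats), seed = split_seed)
  model <- crf_train(feats[sp$train], entity_type, seed = 1, maxit = maxit)
  list(model = model, sentences = feats, split = sp, corpus = corpus)
}

tiny_nn_config <- function(seed = 3, epochs = 12L) {
  nn_config(seed = seed, word_embed_dim = 32L, char_embed_dim = 12L,
            char_word_dim = 24L, word_hidden = 32L, epochs = epochs)
}

# brute-force leftmost-longest dictionary matcher (oracle for dict_match)
bf_dict_match <- function(tokens, dictionary) {
  entry_toks <- lapply(dictionary, function(e) tokenize(e)$surface)
  case_sens <- nchar(dictionary) <= 3L
  n <- nrow(tokens)
  res <- list()
  i <- 1L
  while (i <= n) {
    best <- 0L
    for (j in seq_along(entry_toks)) {
      L <- length(entry_toks[[j]])
      if (L == 0L || i + L - 1L > n || L <= best) next
      seg <- tokens$surface[i:(i + L - 1L)]
      ok <- if (case_sens[j]) identical(seg, entry_toks[[j]])
      else identical(tolower(seg), tolower(entry_toks[[j]]))
      if (ok) best <- L
    }
    if (best > 0L) {
      res[[length(res) + 1L]] <- c(tokens$begin[i], tokens$end[i + best - 1L])
      i <- i + best
    } else i <- i + 1L
  }
  res
}
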