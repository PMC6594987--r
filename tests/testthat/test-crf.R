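test_that("feature rows reproduce the reference sentence and count tokens", {
  toks <- tokenize(TABLE_SENT, mode = "detokenized")
  feat <- build_features(toks, load_dictionary("BrainRegion"), "BrainRegion")
  row <- feat[feat$Word == "ventral", ]
  expect_equal(row$Begin, 67L)
  expect_equal(row$End, 74L)
  expect_equal(row$Lemma, "ventral")
  expect_equal(row$POS, "JJ")
  expect_equal(row$Chunk, "I-NP")
  expect_equal(row$Dict, "B-BrainRegion")
  expect_equal(feat[feat$Word == "were", "Lemma"], "be")
  expect_equal(feat[feat$Word == "made", "Lemma"], "make")
  # tokens absent from the dictionary carry O
  expect_equal(feat[feat$Word == "voltage", "Dict"], "O")
  # row count equals token count on random fixtures
  corpus <- make_corpus(seed = 3, docs = 2, sents = 5)
  for (s in corpus_sentences(corpus, "NeuronType")) {
    expect_equal(nrow(s), length(s$Word))
  }
})

test_that("training memorizes a single sentence and errors on all-O data", {
  toks <- tokenize("recordings from relay cells in the ventrobasal complex")
  gold <- span_annotation(
    "NeuronType", toks$begin[3], toks$end[4], "relay cells")
  feat <- build_features(toks, NULL, "NeuronType", gold = gold)
  m <- crf_train(list(feat), "NeuronType", maxit = 100)
  expect_identical(crf_predict(m, feat), feat$GoldLabel)
  feat0 <- build_features(toks, NULL, "NeuronType")
  expect_error(crf_train(list(feat0), "NeuronType"), "degenerate")
})

test_that("training is deterministic and models survive save/load", {
  fx <- quick_crf(docs = 5, sents = 6, maxit = 50)
  m2 <- crf_train(fx$sentences[fx$split$train], "BrainRegion", seed = 1,
                  maxit = 50)
  expect_identical(fx$model$W, m2$W)
  expect_identical(fx$model$trans, m2$trans)
  p <- withr::local_tempfile(fileext = ".rds")
  crf_save(fx$model, p)
  m3 <- crf_load(p)
  s <- fx$sentences[[fx$split$test[1]]]
  expect_identical(crf_predict(m3, s), crf_predict(fx$model, s))
})

test_that("n-best probabilities are exact conditional probabilities", {
  fx <- quick_crf(docs = 5, sents = 6, maxit = 50)
  m <- fx$model
  feat <- build_features(tokenize("the caudal reticular nucleus responded"),
                         NULL, "BrainRegion")
  len <- nrow(feat)
  all_h <- crf_nbest(m, feat, 3^len)
  probs <- vapply(all_h, `[[`, numeric(1), "probability")
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  expect_true(all(diff(probs) <= 1e-12))
  # brute-force enumeration over all 3^len sequences via the score function
  grid <- as.matrix(expand.grid(rep(list(1:3), len)))
  logZ <- crf_logZ(m, feat)
  bf <- sort(apply(grid, 1, function(y) {
    exp(crf_sequence_score(m, feat, m$labels[y]) - logZ)
  }), decreasing = TRUE)
  expect_equal(sort(probs, decreasing = TRUE), bf, tolerance = 1e-9)
  # N = 1 equals the Viterbi argmax
  expect_identical(crf_nbest(m, feat, 1)[[1]]$labels, crf_predict(m, feat))
  expect_error(crf_nbest(m, feat, 0), ">= 1")
})

test_that("n-best hypothesis probabilities are non-increasing on random sentences", {
  fx <- quick_crf(docs = 5, sents = 6, maxit = 40)
  for (s in fx$sentences[head(fx$split$test, 5)]) {
    hyps <- crf_nbest(fx$model, s, 5)
    probs <- vapply(hyps, `[[`, numeric(1), "probability")
    expect_true(all(diff(probs) <= 1e-12))
    expect_true(all(probs <= 1 + 1e-12))
  }
})

test_that("the dictionary feature column is optional without changing the API", {
  corpus <- make_corpus(seed = 13, docs = 6, sents = 6)
  sents <- corpus_sentences(corpus, "BrainRegion")
  m <- crf_train(sents[1:30], "BrainRegion", use_dict = FALSE, maxit = 50)
  pred <- crf_predict(m, sents[[31]])
  expect_length(pred, nrow(sents[[31]]))
  expect_true(all(pred %in% m$labels))
})

test_that("a held-out test split is tagged with high span F1", {
  fx <- quick_crf(docs = 14, sents = 8, maxit = 120)
  test_sents <- fx$sentences[fx$split$test]
  preds <- lapply(test_sents, function(s) crf_predict(fx$model, s))
  expect_gte(span_f1(test_sents, preds, "BrainRegion"), 0.9)
})
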