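make_nn_sents <- function(docs = 14, seed = 11, type = "BrainRegion") {
  corpus <- make_corpus(seed = seed, docs = docs, sents = 8)
  corpus_sentences(corpus, type)
}

test_that("analytic gradients match finite differences", {
  sents <- list(
    data.frame(Begin = 0L, End = 1L, Word = c("abc", "de", "abc"),
               Lemma = "x", POS = "NN", Chunk = "O", Dict = "O",
               GoldLabel = c("B-Unit", "I-Unit", "O"),
               stringsAsFactors = FALSE),
    data.frame(Begin = 0L, End = 1L, Word = c("de", "fg"),
               Lemma = "x", POS = "NN", Chunk = "O", Dict = "O",
               GoldLabel = c("O", "B-Unit"), stringsAsFactors = FALSE))
  vocab <- build_vocab(sents)
  enc <- neuromine:::.encode_sentences(sents, vocab)
  labels <- c("B-Unit", "I-Unit", "O")
  labs <- lapply(sents, function(s) match(s$GoldLabel, labels))
  p <- neuromine:::nn_init_params_cpp(length(vocab$words), length(vocab$chars),
                                      5L, 3L, 4L, 6L, 3L, 11L)
  lg <- neuromine:::nn_loss_grad_cpp(p, enc$words, enc$chars, labs, 0, 1L)
  eps <- 1e-6
  set.seed(2)
  for (nm in names(p)) {
    g <- lg$grads[[nm]]
    for (i in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + eps
      lp <- neuromine:::nn_loss_grad_cpp(p2, enc$words, enc$chars, labs, 0, 1L)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      lm <- neuromine:::nn_loss_grad_cpp(p2, enc$words, enc$chars, labs, 0, 1L)$loss
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(g[i] - num) / max(1, abs(num)), 1e-5)
    }
  }
})

test_that("word representations concatenate word and character encodings", {
  sents <- make_nn_sents(docs = 3)
  cfg <- tiny_nn_config(epochs = 1L)
  m <- nn_train(sents[1:6], "BrainRegion", cfg)
  v <- encode_word(m, "nucleus")
  expect_length(v, cfg$word_embed_dim + cfg$char_word_dim)
  # single-character word runs both directions over the one-step sequence
  expect_length(encode_word(m, "a"), cfg$word_embed_dim + cfg$char_word_dim)
  expect_error(encode_word(m, ""), "empty word")
  # architecture determinism: same seed, same parameter shapes and values
  m2 <- nn_train(sents[1:6], "BrainRegion", cfg)
  expect_identical(lapply(m$params, dim), lapply(m2$params, dim))
  expect_equal(m$params$out_W, m2$params$out_W)
})

test_that("reversing a word swaps forward and backward character passes (tied weights)", {
  sents <- make_nn_sents(docs = 2)
  cfg <- tiny_nn_config(epochs = 1L)
  m <- nn_train(sents[1:4], "BrainRegion", cfg)
  # tie the two character LSTMs
  m$params$cb_W <- m$params$cf_W
  m$params$cb_U <- m$params$cf_U
  m$params$cb_b <- m$params$cf_b
  h_c <- cfg$char_word_dim / 2
  d_w <- cfg$word_embed_dim
  v1 <- encode_word(m, "abcde")
  v2 <- encode_word(m, "edcba")
  fwd1 <- v1[(d_w + 1):(d_w + h_c)]
  bwd1 <- v1[(d_w + h_c + 1):(d_w + 2 * h_c)]
  fwd2 <- v2[(d_w + 1):(d_w + h_c)]
  bwd2 <- v2[(d_w + h_c + 1):(d_w + 2 * h_c)]
  expect_equal(fwd1, bwd2, tolerance = 1e-12)
  expect_equal(bwd1, fwd2, tolerance = 1e-12)
})

test_that("CRF-layer decoding equals exhaustive argmax and is repeatable", {
  sents <- make_nn_sents(docs = 6)
  m <- nn_train(sents[1:20], "BrainRegion", tiny_nn_config(epochs = 4L))
  short <- lapply(c("the nucleus responded", "dorsal thalamic area",
                    "rats slept quietly overnight"), function(txt) {
    build_features(tokenize(txt), NULL, "BrainRegion")
  })
  for (s in short) {
    em <- nn_emissions(m, s)
    len <- nrow(em$emissions)
    grid <- as.matrix(expand.grid(rep(list(1:3), len)))
    sc <- apply(grid, 1, function(y) {
      v <- em$init[y[1]] + em$emissions[1, y[1]]
      if (len > 1) for (t in 2:len) {
        v <- v + em$trans[y[t - 1], y[t]] + em$emissions[t, y[t]]
      }
      v
    })
    best <- grid[which.max(sc), ]
    expect_identical(nn_tag(m, s), m$labels[best])
  }
  # inference determinism and output length
  s <- sents[[41]]
  expect_identical(nn_tag(m, s), nn_tag(m, s))
  expect_length(nn_tag(m, s), nrow(s))
  empty <- s[0, ]
  expect_length(nn_tag(m, empty), 0L)
})

test_that("training loss is finite and decreases over the first epochs", {
  sents <- make_nn_sents(docs = 8)
  m <- nn_train(sents[1:40], "BrainRegion", tiny_nn_config(epochs = 4L))
  expect_true(all(is.finite(m$epoch_losses)))
  expect_lt(m$epoch_losses[3], m$epoch_losses[1])
})

test_that("the network memorizes a small corpus with dropout disabled", {
  sents <- make_nn_sents(docs = 4)
  with_gold <- head(Filter(function(s) any(s$GoldLabel != "O"), sents), 10L)
  cfg <- tiny_nn_config(epochs = 20L)
  cfg$dropout <- 0
  m <- nn_train(with_gold, "BrainRegion", cfg)
  preds <- nn_tag(m, with_gold)
  expect_gte(span_f1(with_gold, preds, "BrainRegion"), 0.99)
})

test_that("batched training loss equals the sum of per-sentence losses", {
  sents <- make_nn_sents(docs = 4)
  batch <- Filter(function(s) nrow(s) > 0, sents)[1:8]
  m <- nn_train(batch, "BrainRegion", tiny_nn_config(epochs = 1L))
  golds <- lapply(batch, `[[`, "GoldLabel")
  total <- nn_loss(m, batch, golds)
  each <- vapply(seq_along(batch), function(i) {
    nn_loss(m, batch[[i]], golds[[i]])
  }, numeric(1))
  expect_equal(total, sum(each), tolerance = 1e-9)
})

test_that("pretrained embeddings initialize in-vocabulary rows exactly", {
  sents <- make_nn_sents(docs = 3)
  vocab <- build_vocab(sents)
  cfg <- tiny_nn_config(epochs = 1L)
  words <- setdiff(vocab$words, "<UNK>")[1:5]
  set.seed(9)
  emb <- matrix(rnorm(5 * cfg$word_embed_dim), 5,
                dimnames = list(words, NULL))
  p <- withr::local_tempfile(fileext = ".bin")
  write_word2vec_bin(emb, p)
  # independent read-back check of the binary format
  back <- read_word2vec_bin(p)
  expect_equal(back[words, ], emb[words, ], tolerance = 1e-6)
  # rows equal the file's vectors before training (epochs kept aside)
  cfg0 <- cfg
  cfg0$epochs <- 1L
  cfg0$learning_rate <- 1e-12  # effectively frozen for the comparison
  m <- nn_train(sents[1:6], "BrainRegion", cfg0, embeddings = p)
  for (w in words) {
    expect_equal(as.numeric(m$params$Wemb[, match(w, m$vocab$words)]),
                 as.numeric(emb[w, ]), tolerance = 1e-5)
  }
  expect_error(nn_train(sents[1:6], "BrainRegion", cfg,
                        embeddings = "/nonexistent/embeddings.bin"),
               "not found")
})

test_that("models survive save/load with identical predictions", {
  sents <- make_nn_sents(docs = 4)
  m <- nn_train(sents[1:15], "BrainRegion", tiny_nn_config(epochs = 3L))
  p <- withr::local_tempfile(fileext = ".rds")
  nn_save(m, p)
  m2 <- nn_load(p)
  expect_identical(nn_tag(m2, sents[[16]]), nn_tag(m, sents[[16]]))
})
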