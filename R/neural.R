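# BiLSTM-CRF neural tagger: R-side vocabulary handling, configuration and
# training/prediction wrappers around the compiled network.

#' Neural tagger configuration
#'
#' Defaults follow the standard recipe for character-aware BiLSTM-CRF
#' taggers: 20 epochs, batches of 10 sentences, 25-dimensional character
#' embeddings, 200-dimensional word embeddings, a 250-dimensional
#' character-based word representation (125 hidden units per direction of
#' the character BiLSTM), dropout 0.5 on the concatenated representation,
#' and Adam with learning rate 0.013 and weight decay 1e-4. The word-level
#' BiLSTM hidden size (per direction) is configurable; the
#' character-based-word dimension must be even since it is the
#' concatenation of the two character LSTM final states.
#'
#' @param epochs,batch Training schedule.
#' @param char_embed_dim,word_embed_dim,char_word_dim,word_hidden
#'   Architecture sizes.
#' @param dropout Dropout rate on the word representation, in `[0, 1)`.
#' @param learning_rate,weight_decay Adam settings.
#' @param seed Seed covering parameter init, dropout masks and shuffling.
#' @return Named list of validated settings.
#' @export
nn_config <- function(epochs = 20L, batch = 10L, char_embed_dim = 25L,
                      word_embed_dim = 200L, char_word_dim = 250L,
                      word_hidden = 100L, dropout = 0.5,
                      learning_rate = 0.013, weight_decay = 1e-4,
                      seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch = as.integer(batch),
              char_embed_dim = as.integer(char_embed_dim),
              word_embed_dim = as.integer(word_embed_dim),
              char_word_dim = as.integer(char_word_dim),
              word_hidden = as.integer(word_hidden),
              dropout = dropout, learning_rate = learning_rate,
              weight_decay = weight_decay, seed = as.integer(seed))
  stopifnot(cfg$epochs > 0, cfg$batch > 0, cfg$char_embed_dim > 0,
            cfg$word_embed_dim > 0, cfg$char_word_dim > 0,
            cfg$word_hidden > 0, cfg$dropout >= 0, cfg$dropout < 1,
            cfg$learning_rate > 0, cfg$weight_decay >= 0)
  if (cfg$char_word_dim %% 2L != 0L) {
    stop("char_word_dim must be even (it concatenates two directions)")
  }
  cfg
}

.UNK <- "<UNK>"

#' Build word and character vocabularies from featurized sentences
#'
#' Every training token receives a word id and per-character ids; an unknown
#' id is reserved for out-of-vocabulary words and characters at prediction
#' time.
#'
#' @param sentences List of featurized sentences with a `Word` column.
#' @return List with `words` and `chars` character vectors (first entry the
#'   unknown marker).
#' @export
build_vocab <- function(sentences) {
  words <- unique(unlist(lapply(sentences, `[[`, "Word")))
  chars <- unique(unlist(strsplit(words, "", fixed = TRUE)))
  list(words = c(.UNK, words), chars = c(.UNK, chars))
}

.encode_sentences <- function(sentences, vocab) {
  word_ids <- lapply(sentences, function(s) {
    ids <- match(s$Word, vocab$words)
    ids[is.na(ids)] <- 1L
    ids
  })
  char_ids <- lapply(sentences, function(s) {
    lapply(s$Word, function(w) {
      if (!nzchar(w)) stop("cannot encode an empty word")
      ids <- match(strsplit(w, "", fixed = TRUE)[[1]], vocab$chars)
      ids[is.na(ids)] <- 1L
      ids
    })
  })
  list(words = word_ids, chars = char_ids)
}

#' Train the BiLSTM-CRF tagger for one entity type
#'
#' The loss is the CRF negative log-likelihood of the gold BIO sequences;
#' dropout is applied to the concatenated word + character representation
#' before the word BiLSTM. Training is deterministic given the seed. When a
#' pretrained embedding table is supplied, in-vocabulary rows initialize the
#' word embeddings and unknown words stay randomly initialized; naming a
#' file that cannot be read is an explicit error, never a silent fallback.
#'
#' @param sentences List of featurized sentences ([build_features()]) with
#'   gold BIO labels in `GoldLabel`.
#' @param entity_type Entity type of the model.
#' @param config From [nn_config()].
#' @param embeddings Optional pretrained embeddings: a path to a word2vec
#'   binary file, or a numeric matrix with words as row names.
#' @return Object of class `nm_bilstm`.
#' @export
nn_train <- function(sentences, entity_type, config = nn_config(),
                     embeddings = NULL) {
  labels <- .crf_labels(entity_type)
  vocab <- build_vocab(sentences)
  enc <- .encode_sentences(sentences, vocab)
  lab_ids <- lapply(sentences, function(s) {
    ids <- match(s$GoldLabel, labels)
    if (anyNA(ids)) stop("gold labels outside {", paste(labels, collapse = ","), "}")
    ids
  })
  h_c <- config$char_word_dim %/% 2L
  params <- nn_init_params_cpp(length(vocab$words), length(vocab$chars),
                               config$word_embed_dim, config$char_embed_dim,
                               h_c, config$word_hidden, 3L, config$seed)
  if (!is.null(embeddings)) {
    emb <- if (is.character(embeddings)) {
      read_word2vec_bin(embeddings, vocab = vocab$words)
    } else embeddings
    if (is.null(rownames(emb))) stop("embedding matrix needs word row names")
    if (ncol(emb) != config$word_embed_dim) {
      stop(sprintf("embedding dimension %d does not match word_embed_dim %d",
                   ncol(emb), config$word_embed_dim))
    }
    hit <- intersect(rownames(emb), vocab$words)
    for (w in hit) {
      params$Wemb[, match(w, vocab$words)] <- emb[w, ]
    }
  }
  fit <- nn_train_cpp(params, enc$words, enc$chars, lab_ids, config)
  structure(list(entity_type = entity_type, labels = labels, vocab = vocab,
                 config = config, params = fit$params,
                 epoch_losses = as.numeric(fit$epoch_losses)),
            class = "nm_bilstm")
}

#' @export
print.nm_bilstm <- function(x, ...) {
  cat(sprintf("<nm_bilstm %s: |V|=%d words, %d epochs, final loss %.3f>\n",
              x$entity_type, length(x$vocab$words), x$config$epochs,
              tail(x$epoch_losses, 1)))
  invisible(x)
}

#' Tag a featurized sentence with a trained neural model
#'
#' Dropout is disabled at inference; the CRF layer decodes the globally best
#' label sequence (ties broken toward the lower label index, B < I < O).
#'
#' @param model `nm_bilstm` model.
#' @param feat Featurized sentence (or list of sentences).
#' @return Character vector of BIO labels (or list thereof).
#' @export
nn_tag <- function(model, feat) {
  single <- is.data.frame(feat)
  sents <- if (single) list(feat) else feat
  nonempty <- vapply(sents, nrow, integer(1)) > 0L
  out <- rep(list(character(0)), length(sents))
  if (any(nonempty)) {
    enc <- .encode_sentences(sents[nonempty], model$vocab)
    pred <- nn_predict_cpp(model$params, enc$words, enc$chars)
    out[nonempty] <- lapply(pred, function(ids) model$labels[ids])
  }
  if (single) out[[1L]] else out
}

#' Emissions and CRF parameters for a sentence (inference mode)
#'
#' Exposes the unnormalized per-token label scores together with the CRF
#' transition and initial weights, so the decoder can be checked against
#' exhaustive enumeration.
#'
#' @inheritParams nn_tag
#' @return List with `emissions` (tokens x 3), `trans` (3 x 3), `init`.
#' @export
nn_emissions <- function(model, feat) {
  enc <- .encode_sentences(list(feat), model$vocab)
  fwd <- nn_forward_cpp(model$params, enc$words, enc$chars)
  list(emissions = fwd$sentences[[1L]]$emissions,
       trans = fwd$trans, init = as.numeric(fwd$init))
}

#' Per-sentence CRF loss under a neural model
#'
#' @inheritParams nn_tag
#' @param labels Gold BIO labels for the sentence(s).
#' @param dropout Dropout rate (0 disables; nonzero draws seeded masks).
#' @param seed Mask seed when `dropout > 0`.
#' @return Total negative log-likelihood over the sentences.
#' @export
nn_loss <- function(model, feat, labels, dropout = 0, seed = 1L) {
  sents <- if (is.data.frame(feat)) list(feat) else feat
  labs <- if (is.character(labels)) list(labels) else labels
  enc <- .encode_sentences(sents, model$vocab)
  lab_ids <- lapply(labs, function(l) match(l, model$labels))
  nn_loss_grad_cpp(model$params, enc$words, enc$chars, lab_ids,
                   dropout, as.integer(seed))$loss
}

#' Character-aware word representation
#'
#' The representation of a word is the concatenation of its word embedding
#' with the final forward and backward states of the character BiLSTM; its
#' length is `word_embed_dim + char_word_dim`.
#'
#' @param model `nm_bilstm` model.
#' @param word Non-empty word string.
#' @return Numeric vector.
#' @export
encode_word <- function(model, word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (!nzchar(word)) stop("cannot encode an empty word")
  feat <- data.frame(Begin = 0L, End = nchar(word), Word = word,
                     Lemma = word, POS = "NN", Chunk = "B-NP", Dict = "O",
                     GoldLabel = "O", stringsAsFactors = FALSE)
  enc <- .encode_sentences(list(feat), model$vocab)
  fwd <- nn_forward_cpp(model$params, enc$words, enc$chars)
  as.numeric(fwd$sentences[[1L]]$repr[, 1L])
}

#' Save / load a neural model
#' @param model `nm_bilstm` model.
#' @param path File path.
#' @export
nn_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname nn_save
#' @export
nn_load <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "nm_bilstm"))
  m
}

#' Read a word2vec binary embedding file
#'
#' Parses the standard word2vec binary format: an ASCII header
#' `"<vocab> <dim>\n"` followed by, per word, the whitespace-terminated word
#' and `dim` little-endian 32-bit floats.
#'
#' @param path File path.
#' @param vocab Optional character vector; only these words are kept.
#' @param max_words Cap on the number of words read.
#' @return Numeric matrix with words as row names.
#' @export
read_word2vec_bin <- function(path, vocab = NULL, max_words = Inf) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated word2vec header")
    if (ch == "\n") break
    header <- c(header, ch)
  }
  hd <- strsplit(trimws(paste(header, collapse = "")), "\\s+")[[1]]
  n_words <- as.integer(hd[1]); dim <- as.integer(hd[2])
  if (is.na(n_words) || is.na(dim)) stop("malformed word2vec header")
  keep <- list()
  for (i in seq_len(min(n_words, max_words))) {
    wchars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("truncated word2vec entry")
      if (b == as.raw(0x20)) break
      if (b != as.raw(0x0a)) wchars <- c(wchars, b)
    }
    word <- rawToChar(wchars)
    Encoding(word) <- "UTF-8"
    vecs <- readBin(con, "numeric", n = dim, size = 4L, endian = "little")
    if (length(vecs) < dim) stop("truncated vector for word ", word)
    if (is.null(vocab) || word %in% vocab) keep[[word]] <- vecs
  }
  if (length(keep) == 0L) {
    return(matrix(numeric(0), 0, dim, dimnames = list(NULL, NULL)))
  }
  out <- do.call(rbind, keep)
  rownames(out) <- names(keep)
  out
}

#' Write embeddings in word2vec binary format
#'
#' Companion writer used to exercise the reader round trip.
#'
#' @param mat Numeric matrix with words as row names.
#' @param path Output file path.
#' @export
write_word2vec_bin <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%d %d\n", nrow(mat), ncol(mat)), con, eos = NULL)
  for (i in seq_len(nrow(mat))) {
    writeChar(paste0(rownames(mat)[i], " "), con, eos = NULL)
    writeBin(as.numeric(mat[i, ]), con, size = 4L, endian = "little")
  }
  invisible(path)
}
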