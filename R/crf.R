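# Linear-chain conditional random field with N-best decoding.
#
# One model is trained per entity type over three labels (B-T, I-T, O).
# Emission features are sparse indicators on word/lemma/POS/chunk/dictionary
# columns in a +-2 token window; transitions are a dense 3x3 matrix plus an
# initial-label term. Training minimizes the L2-penalized negative
# log-likelihood with L-BFGS using exact forward-backward gradients, so the
# decoder's conditional probabilities are true probabilities under the model.

#' Build the per-token feature rows for a sentence
#'
#' Produces the seven-column feature schema consumed by the CRF: character
#' offsets, raw word, lemma, POS tag, chunk tag, and a BIO dictionary-match
#' column for the active entity type, plus a gold-label column (all `O` when
#' no gold annotations are given).
#'
#' @param tokens Token data.frame for one sentence.
#' @param dictionary Entry vector for the active entity type (`NULL` for an
#'   all-`O` dictionary column).
#' @param entity_type Active entity type.
#' @param gold Optional span annotation table aligned with the tokens'
#'   offsets, used to fill `GoldLabel`.
#' @return data.frame with columns
#'   `Begin End Word Lemma POS Chunk Dict GoldLabel`.
#' @export
build_features <- function(tokens, dictionary = NULL, entity_type,
                           gold = NULL) {
  if (nrow(tokens) == 0L) {
    out <- data.frame(Begin = integer(0), End = integer(0), Word = character(0),
                      Lemma = character(0), POS = character(0),
                      Chunk = character(0), Dict = character(0),
                      GoldLabel = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  pos <- pos_tag(tokens$surface)
  lemma <- lemmatize(tokens$surface, pos)
  chunk <- chunk_tags(tokens$surface, pos)
  dict_bio <- rep("O", nrow(tokens))
  if (!is.null(dictionary) && length(dictionary)) {
    spans <- dict_match(tokens, dictionary, entity_type)
    dict_bio <- spans_to_bio(tokens, spans, entity_type)
  }
  gold_bio <- rep("O", nrow(tokens))
  if (!is.null(gold) && nrow(gold)) {
    gold_bio <- spans_to_bio(tokens, gold, entity_type)
  }
  data.frame(Begin = tokens$begin, End = tokens$end, Word = tokens$surface,
             Lemma = lemma, POS = pos, Chunk = chunk, Dict = dict_bio,
             GoldLabel = gold_bio, stringsAsFactors = FALSE)
}

.crf_labels <- function(entity_type) {
  c(paste0("B-", entity_type), paste0("I-", entity_type), "O")
}

# active feature strings for every token of a featurized sentence
.token_features <- function(feat, window = 2L, use_dict = TRUE) {
  cols <- c(W = "Word", L = "Lemma", P = "POS", C = "Chunk",
            if (use_dict) c(D = "Dict"))
  n <- nrow(feat)
  pad <- function(v) c(rep("<S>", window), v, rep("</S>", window))
  padded <- lapply(cols, function(cl) pad(feat[[cl]]))
  lapply(seq_len(n), function(t) {
    fs <- c("bias")
    for (ci in seq_along(cols)) {
      nm <- names(cols)[ci]
      for (d in -window:window) {
        fs <- c(fs, paste0(nm, "[", d, "]=", padded[[ci]][t + window + d]))
      }
    }
    fs
  })
}

# sparse design matrix (rows = tokens across sentences) over a feature index
.design_matrix <- function(feature_lists, index) {
  n_tok <- length(feature_lists)
  ii <- integer(0); jj <- integer(0)
  for (t in seq_len(n_tok)) {
    ids <- index[feature_lists[[t]]]
    ids <- ids[!is.na(ids)]
    ii <- c(ii, rep.int(t, length(ids)))
    jj <- c(jj, ids)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(n_tok, length(index)))
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# forward-backward for one sentence; E is n x 3 emissions
.crf_fb <- function(E, trans, init) {
  n <- nrow(E); L <- ncol(E)
  alpha <- matrix(0, n, L); beta <- matrix(0, n, L)
  alpha[1L, ] <- init + E[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      for (y in 1:L) {
        alpha[t, y] <- E[t, y] + .logsumexp(alpha[t - 1L, ] + trans[, y])
      }
    }
    for (t in (n - 1L):1L) {
      for (y in 1:L) {
        beta[t, y] <- .logsumexp(trans[y, ] + E[t + 1L, ] + beta[t + 1L, ])
      }
    }
  }
  logZ <- .logsumexp(alpha[n, ])
  list(alpha = alpha, beta = beta, logZ = logZ)
}

#' Train a CRF tagger for one entity type
#'
#' @param sentences List of featurized sentences ([build_features()] output)
#'   whose `GoldLabel` column holds the BIO gold labels.
#' @param entity_type Entity type of the model.
#' @param window Feature window half-width in tokens (default 2).
#' @param use_dict Include the dictionary BIO column as a feature.
#' @param c L2 regularization scale; the penalty is `||w||^2 / (2c)`.
#' @param maxit Maximum L-BFGS iterations.
#' @param seed Recorded in the model metadata (training itself is
#'   deterministic given the data order).
#' @return An object of class `nm_crf`.
#' @export
crf_train <- function(sentences, entity_type, window = 2L, use_dict = TRUE,
                      c = 1.0, maxit = 150L, seed = 1L) {
  labels <- .crf_labels(entity_type)
  golds <- lapply(sentences, function(s) s$GoldLabel)
  if (!any(unlist(golds) != "O")) {
    stop("degenerate training data: every gold label is O")
  }
  if (!all(unlist(golds) %in% labels)) {
    stop("gold labels outside {", paste(labels, collapse = ","), "}")
  }
  feats <- unlist(lapply(sentences, .token_features, window = window,
                         use_dict = use_dict), recursive = FALSE)
  fnames <- unique(unlist(feats))
  index <- setNames(seq_along(fnames), fnames)
  X <- .design_matrix(feats, index)
  lens <- vapply(sentences, nrow, integer(1))
  offs <- cumsum(c(0L, lens))
  y <- unlist(lapply(golds, function(g) match(g, labels)))
  n_tok <- nrow(X); Fn <- length(fnames); L <- 3L
  Y1 <- Matrix::sparseMatrix(i = seq_len(n_tok), j = y, x = 1,
                             dims = c(n_tok, L))
  emp_emit <- as.matrix(Matrix::crossprod(X, Y1))
  emp_trans <- matrix(0, L, L); emp_init <- numeric(L)
  for (s in seq_along(sentences)) {
    ys <- y[(offs[s] + 1L):offs[s + 1L]]
    emp_init[ys[1L]] <- emp_init[ys[1L]] + 1
    if (length(ys) > 1L) {
      for (t in 2:length(ys)) {
        emp_trans[ys[t - 1L], ys[t]] <- emp_trans[ys[t - 1L], ys[t]] + 1
      }
    }
  }
  npar_w <- Fn * L
  unpack <- function(th) {
    list(W = matrix(th[seq_len(npar_w)], Fn, L),
         trans = matrix(th[npar_w + 1:9], L, L),
         init = th[npar_w + 9 + 1:3])
  }
  l2 <- 1 / c
  cache <- new.env(parent = emptyenv())
  objective <- function(th) {
    p <- unpack(th)
    Eall <- as.matrix(X %*% p$W)
    nll <- 0
    g_emit_resid <- matrix(0, n_tok, L)
    g_trans <- matrix(0, L, L); g_init <- numeric(L)
    for (s in seq_along(sentences)) {
      rows <- (offs[s] + 1L):offs[s + 1L]
      E <- Eall[rows, , drop = FALSE]
      fb <- .crf_fb(E, p$trans, p$init)
      ys <- y[rows]
      score <- p$init[ys[1L]] + E[1L, ys[1L]]
      if (length(ys) > 1L) {
        for (t in 2:length(ys)) {
          score <- score + p$trans[ys[t - 1L], ys[t]] + E[t, ys[t]]
        }
      }
      nll <- nll + (fb$logZ - score)
      marg <- exp(fb$alpha + fb$beta - fb$logZ)
      g_emit_resid[rows, ] <- marg
      g_init <- g_init + marg[1L, ]
      n <- length(ys)
      if (n > 1L) {
        for (t in 2:n) {
          pm <- exp(outer(fb$alpha[t - 1L, ], E[t, ] + fb$beta[t, ], "+") +
                      p$trans - fb$logZ)
          g_trans <- g_trans + pm
        }
      }
    }
    gW <- as.matrix(Matrix::crossprod(X, g_emit_resid)) - emp_emit + l2 * p$W
    gT <- g_trans - emp_trans + l2 * p$trans
    gI <- g_init - emp_init + l2 * p$init
    cache$grad <- c(as.vector(gW), as.vector(gT), gI)
    nll + 0.5 * l2 * sum(th^2)
  }
  gradient <- function(th) cache$grad
  th0 <- numeric(npar_w + 12L)
  fit <- optim(th0, fn = objective, gr = gradient, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  p <- unpack(fit$par)
  structure(list(entity_type = entity_type, labels = labels,
                 feature_names = fnames, feature_index = index,
                 W = p$W, trans = p$trans,
                 init = p$init, window = window, use_dict = use_dict,
                 c = c, seed = seed, converged = fit$convergence == 0,
                 nll = fit$value),
            class = "nm_crf")
}

#' @export
print.nm_crf <- function(x, ...) {
  cat(sprintf("<nm_crf %s: %d features, window %d, penalized NLL %.3f>\n",
              x$entity_type, length(x$feature_names), x$window, x$nll))
  invisible(x)
}

# emissions for a featurized sentence under a model (unknown features drop out)
.crf_emissions <- function(model, feat) {
  fls <- .token_features(feat, window = model$window,
                         use_dict = model$use_dict)
  index <- model$feature_index
  if (is.null(index)) {
    index <- setNames(seq_along(model$feature_names), model$feature_names)
  }
  n <- length(fls)
  E <- matrix(0, n, 3L)
  for (t in seq_len(n)) {
    ids <- index[fls[[t]]]
    ids <- ids[!is.na(ids)]
    if (length(ids)) E[t, ] <- colSums(model$W[ids, , drop = FALSE])
  }
  E
}

#' Unnormalized model score of a full label sequence
#'
#' The sum of initial, transition and emission weights along the path; the
#' conditional probability of the sequence is
#' `exp(score - log Z)`.
#'
#' @param model `nm_crf` model.
#' @param feat Featurized sentence.
#' @param labels BIO label vector.
#' @return Numeric scalar score (log potential).
#' @export
crf_sequence_score <- function(model, feat, labels) {
  E <- .crf_emissions(model, feat)
  ys <- match(labels, model$labels)
  stopifnot(!anyNA(ys), length(ys) == nrow(E))
  score <- model$init[ys[1L]] + E[1L, ys[1L]]
  if (length(ys) > 1L) {
    for (t in 2:length(ys)) {
      score <- score + model$trans[ys[t - 1L], ys[t]] + E[t, ys[t]]
    }
  }
  score
}

#' Log partition function of a sentence under the model
#' @inheritParams crf_sequence_score
#' @return `log Z(x)`.
#' @export
crf_logZ <- function(model, feat) {
  E <- .crf_emissions(model, feat)
  .crf_fb(E, model$trans, model$init)$logZ
}

#' N-best label sequences with conditional probabilities
#'
#' Exact k-best Viterbi decoding over the chain. Hypotheses are returned in
#' non-increasing probability order; equal-scoring hypotheses are ordered by
#' lexicographically smaller label sequence (B < I < O). The probabilities
#' are exact conditional probabilities `P(y|x)` (they sum to 1 over all
#' `3^n` sequences).
#'
#' @param model `nm_crf` model.
#' @param feat Featurized sentence.
#' @param n Number of hypotheses requested (`n >= 1`).
#' @return List of hypotheses, each `list(labels = <chr>, probability =
#'   <dbl>)`; at most `min(n, 3^len)` entries.
#' @export
crf_nbest <- function(model, feat, n = 3L) {
  if (n < 1L) stop("n must be >= 1")
  L <- 3L
  len <- nrow(feat)
  if (len == 0L) return(list())
  E <- .crf_emissions(model, feat)
  logZ <- .crf_fb(E, model$trans, model$init)$logZ
  # beam[[y]] = list of hypotheses ending in label y: list(score, path)
  beam <- lapply(1:L, function(y) list(list(score = model$init[y] + E[1L, y],
                                            path = y)))
  if (len > 1L) {
    for (t in 2:len) {
      nb <- vector("list", L)
      for (yc in 1:L) {
        cands <- list()
        for (yp in 1:L) {
          for (h in beam[[yp]]) {
            cands[[length(cands) + 1L]] <- list(
              score = h$score + model$trans[yp, yc] + E[t, yc],
              path = c(h$path, yc))
          }
        }
        nb[[yc]] <- .top_hyps(cands, n)
      }
      beam <- nb
    }
  }
  final <- .top_hyps(unlist(beam, recursive = FALSE), n)
  lapply(final, function(h) {
    list(labels = model$labels[h$path],
         probability = exp(h$score - logZ))
  })
}

# order hypotheses by score desc, ties by lexicographic path (B<I<O), keep k
.top_hyps <- function(hyps, k) {
  if (length(hyps) == 0L) return(hyps)
  scores <- vapply(hyps, `[[`, numeric(1), "score")
  keys <- vapply(hyps, function(h) paste(h$path, collapse = ""), character(1))
  ord <- order(-scores, keys)
  hyps[ord[seq_len(min(k, length(hyps)))]]
}

#' Predict BIO labels for a featurized sentence
#'
#' The Viterbi argmax, equal to the first hypothesis of [crf_nbest()].
#'
#' @inheritParams crf_nbest
#' @return Character vector of labels.
#' @export
crf_predict <- function(model, feat) {
  if (nrow(feat) == 0L) return(character(0))
  crf_nbest(model, feat, 1L)[[1L]]$labels
}

#' Save / load a CRF model
#'
#' The container is self-describing: entity type, feature template settings,
#' seed and weights all round-trip.
#'
#' @param model `nm_crf` model.
#' @param path File path.
#' @export
crf_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname crf_save
#' @export
crf_load <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "nm_crf"))
  m
}
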