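# Uncertainty-based active learning: normalized N-best sequence entropy.

#' Normalized N-best sequence entropy
#'
#' Given the conditional probabilities of the top-N predicted label
#' sequences for a sentence, the probabilities are renormalized by their
#' sum, their Shannon entropy is taken in log base 2, and the result is
#' divided by `log2(N)` so the score lies in `[0, 1]`. A uniform top-N
#' scores 1; all mass on one sequence scores 0 (with `0 * log 0 = 0`).
#'
#' When the decoder returns fewer than `N` hypotheses (short sentences have
#' fewer than `N` possible sequences), the entropy sum runs over the actual
#' hypotheses but the denominator stays at `log2(N)`, keeping scores
#' comparable across sentences.
#'
#' @param probabilities Conditional probabilities of the top hypotheses
#'   (non-negative; trailing zeros allowed).
#' @param N Nominal hypothesis count used for normalization (default the
#'   number of probabilities supplied).
#' @return Normalized entropy in `[0, 1]`.
#' @export
normalized_entropy <- function(probabilities, N = length(probabilities)) {
  if (length(probabilities) == 0L) stop("no probabilities supplied")
  if (any(probabilities < 0)) stop("probabilities must be non-negative")
  if (length(probabilities) > N) stop("more probabilities than N")
  if (N < 2L) return(0)
  s <- sum(probabilities)
  if (s <= 0) stop("probabilities sum to zero")
  p <- probabilities / s
  terms <- ifelse(p > 0, p * log2(p), 0)
  h <- -sum(terms)
  min(max(h / log2(N), 0), 1)
}

#' Score sentences in an unlabelled pool by normalized entropy
#'
#' @param pool List of featurized sentences ([build_features()] output).
#' @param model Trained `nm_crf` model.
#' @param N Number of hypotheses per sentence (default 3).
#' @return Numeric vector of scores in `[0, 1]`, one per sentence.
#' @export
score_pool <- function(pool, model, N = 3L) {
  vapply(pool, function(feat) {
    if (nrow(feat) == 0L) return(0)
    hyps <- crf_nbest(model, feat, N)
    normalized_entropy(vapply(hyps, `[[`, numeric(1), "probability"), N)
  }, numeric(1))
}

#' Select the most informative sentences for annotation
#'
#' Ranks an unlabelled pool by normalized N-best entropy under the current
#' model and returns the top-K indices, ranked by descending score; ties
#' break by pool order, so selection is deterministic.
#'
#' @param pool List of featurized sentences.
#' @param model Trained `nm_crf` model.
#' @param N Hypotheses per sentence (default 3, the configuration used for
#'   corpus construction).
#' @param K Batch size (default 500).
#' @return data.frame with `index` (into the pool) and `score`, at most `K`
#'   rows, ordered by decreasing score.
#' @export
select_batch <- function(pool, model, N = 3L, K = 500L) {
  if (K < 1L) stop("K must be >= 1")
  if (!inherits(model, "nm_crf")) stop("model must be a trained nm_crf")
  if (length(pool) == 0L) {
    return(data.frame(index = integer(0), score = numeric(0)))
  }
  scores <- score_pool(pool, model, N)
  ord <- order(-scores, seq_along(scores))
  top <- ord[seq_len(min(K, length(scores)))]
  data.frame(index = top, score = scores[top])
}
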