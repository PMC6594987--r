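# Strict and relaxed span evaluation, inter-annotator agreement, and the
# train/test/validate corpus split.

#' Precision, recall and F1 for predicted spans
#'
#' Strict matching requires exact `(begin, end)` equality with a gold span;
#' relaxed matching accepts any character overlap. Each gold span is matched
#' at most once, by greedy left-to-right pairing, so several predictions
#' overlapping one gold span yield one true positive and extra false
#' positives. With no predictions precision is defined as 0 (not 1).
#'
#' @param predicted,gold Span annotation tables sharing one coordinate
#'   system and one entity type.
#' @param mode `"strict"` or `"relaxed"`.
#' @return List of class `nm_eval`: `entity_type`, `mode`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`.
#' @export
prf <- function(predicted, gold, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  types <- unique(c(predicted$entity_type, gold$entity_type))
  if (length(types) > 1L) {
    stop("prf() scores one entity type at a time; got: ",
         paste(types, collapse = ", "))
  }
  pred <- predicted[order(predicted$begin, predicted$end), , drop = FALSE]
  gld <- gold[order(gold$begin, gold$end), , drop = FALSE]
  matched_gold <- rep(FALSE, nrow(gld))
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    b <- pred$begin[i]; e <- pred$end[i]
    hit <- if (mode == "strict") {
      which(!matched_gold & gld$begin == b & gld$end == e)
    } else {
      which(!matched_gold & gld$begin < e & gld$end > b)
    }
    if (length(hit)) {
      matched_gold[hit[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(pred) - tp
  fn <- nrow(gld) - tp
  precision <- if (nrow(pred) == 0L) 0 else tp / nrow(pred)
  recall <- if (nrow(gld) == 0L) 0 else tp / nrow(gld)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(entity_type = if (length(types)) types else NA_character_,
                 mode = mode, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1),
            class = "nm_eval")
}

#' @export
print.nm_eval <- function(x, ...) {
  cat(sprintf("<%s %s: P=%.3f R=%.3f F1=%.3f (tp=%d fp=%d fn=%d)>\n",
              x$entity_type, x$mode, x$precision, x$recall, x$f1,
              x$tp, x$fp, x$fn))
  invisible(x)
}

#' Per-type evaluation over multi-type annotation tables
#'
#' @inheritParams prf
#' @param types Entity types to score (default: all present in gold or
#'   predictions).
#' @return data.frame with one row per type plus an `"All"` row pooling the
#'   counts (micro average).
#' @export
prf_by_type <- function(predicted, gold, mode = c("strict", "relaxed"),
                        types = NULL) {
  mode <- match.arg(mode)
  if (is.null(types)) {
    types <- sort(unique(c(predicted$entity_type, gold$entity_type)))
  }
  rows <- lapply(types, function(ty) {
    r <- prf(predicted[predicted$entity_type == ty, , drop = FALSE],
             gold[gold$entity_type == ty, , drop = FALSE], mode)
    data.frame(entity_type = ty, tp = r$tp, fp = r$fp, fn = r$fn,
               precision = r$precision, recall = r$recall, f1 = r$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tp <- sum(out$tp); fp <- sum(out$fp); fn <- sum(out$fn)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  rbind(out, data.frame(entity_type = "All", tp = tp, fp = fp, fn = fn,
                        precision = p, recall = r, f1 = f,
                        stringsAsFactors = FALSE))
}

#' Inter-annotator agreement as F1
#'
#' Strict-match F1 between two annotators' span sets over the same
#' documents, treating annotator A as the reference. Only annotated spans
#' enter the score; agreement on unannotated text is never rewarded. F1 is
#' symmetric under exchanging the annotators (precision and recall swap).
#'
#' @param ann_a,ann_b Named lists of span annotation tables, one element per
#'   document (names are document ids), or plain tables for a single shared
#'   document.
#' @return data.frame as [prf_by_type()], computed over all documents.
#' @export
agreement_f1 <- function(ann_a, ann_b) {
  if (is.data.frame(ann_a)) ann_a <- list(doc = ann_a)
  if (is.data.frame(ann_b)) ann_b <- list(doc = ann_b)
  if (!setequal(names(ann_a), names(ann_b))) {
    stop("annotators must cover the same document set")
  }
  shift <- 0L
  a_all <- list(); b_all <- list()
  for (id in names(ann_a)) {
    a <- ann_a[[id]]; b <- ann_b[[id]]
    a$begin <- a$begin + shift; a$end <- a$end + shift
    b$begin <- b$begin + shift; b$end <- b$end + shift
    top <- max(0L, a$end, b$end)
    shift <- top + 1L
    a_all[[id]] <- a; b_all[[id]] <- b
  }
  prf_by_type(do.call(rbind, b_all), do.call(rbind, a_all), mode = "strict")
}

#' Split a corpus into train, test and validate partitions
#'
#' Sentences are shuffled with the seed, then partitioned by the rounded
#' ratio shares; rounding remainders go to the training partition. The
#' partitions are disjoint and cover the input.
#'
#' @param n Number of sentences, or a list whose length is used.
#' @param ratios Numeric length-3 vector `(train, test, validate)` summing
#'   to 1; default `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed for the shuffle.
#' @return List with integer index vectors `train`, `test`, `validate`.
#' @export
split_corpus <- function(n, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  if (!is.numeric(n)) n <- length(n)
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three shares summing to 1")
  }
  perm <- .with_seed(seed, sample.int(n))
  n_test <- round(ratios[2L] * n)
  n_val <- round(ratios[3L] * n)
  n_train <- n - n_test - n_val
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[n_train + seq_len(n_test)]),
       validate = sort(perm[n_train + n_test + seq_len(n_val)]))
}

# evaluate an expression under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
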