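#' Encode token-aligned spans as a BIO label sequence
#'
#' For a single entity type T, the first token of each span is labelled
#' `B-T`, subsequent covered tokens `I-T`, and every other token `O`.
#' Annotations of other entity types are ignored.
#'
#' A span whose boundary falls strictly inside a token either aborts
#' (`boundary_policy = "reject"`) or is snapped outward to the enclosing
#' token boundaries with a warning (the default).
#'
#' @param tokens Token data.frame (see [tokenize()]); offsets must share the
#'   annotations' coordinate system.
#' @param annotations Span annotation table.
#' @param entity_type The entity type to encode.
#' @param boundary_policy `"snap"` (default) or `"reject"`.
#' @return Character vector of labels, one per token.
#' @export
spans_to_bio <- function(tokens, annotations, entity_type,
                         boundary_policy = c("snap", "reject")) {
  boundary_policy <- match.arg(boundary_policy)
  labels <- rep("O", nrow(tokens))
  ann <- annotations[annotations$entity_type == entity_type, , drop = FALSE]
  if (nrow(ann) == 0L) return(labels)
  for (i in seq_len(nrow(ann))) {
    b <- ann$begin[i]; e <- ann$end[i]
    covered <- which(tokens$end > b & tokens$begin < e)
    if (length(covered) == 0L) next
    aligned <- tokens$begin[covered[1L]] == b &&
      tokens$end[covered[length(covered)]] == e
    if (!aligned) {
      if (boundary_policy == "reject") {
        stop(sprintf("annotation [%d,%d) '%s' crosses a token boundary",
                     b, e, ann$surface[i]))
      }
      warning(sprintf("annotation [%d,%d) snapped outward to token boundaries",
                      b, e), call. = FALSE)
    }
    labels[covered[1L]] <- paste0("B-", entity_type)
    if (length(covered) > 1L) {
      labels[covered[-1L]] <- paste0("I-", entity_type)
    }
  }
  labels
}

#' Decode a BIO label sequence into span annotations
#'
#' Maximal `B,I,...` runs become spans; the span begins at the first token's
#' begin offset and ends at the last token's end offset. A dangling `I-`
#' label (one not preceded by `B-` or `I-` of the same type) is repaired to
#' `B-`, with a warning, so decoding is total.
#'
#' @param tokens Token data.frame aligned with `labels`.
#' @param labels BIO label vector (`B-T`/`I-T`/`O`).
#' @param entity_type Entity type of the sequence; also accepted as bare
#'   `B`/`I` labels.
#' @param source Provenance recorded on the decoded spans.
#' @return Span annotation table.
#' @export
bio_to_spans <- function(tokens, labels, entity_type, source = "gold") {
  if (length(labels) != nrow(tokens)) {
    stop(sprintf("label/token length mismatch: %d labels for %d tokens",
                 length(labels), nrow(tokens)))
  }
  if (length(labels) == 0L) return(empty_annotations())
  kind <- sub("-.*$", "", labels)  # B / I / O
  if (!all(kind %in% c("B", "I", "O"))) stop("labels must be B-*, I-* or O")
  # repair dangling I -> B
  prev <- c("O", kind[-length(kind)])
  dangle <- which(kind == "I" & prev == "O")
  if (length(dangle)) {
    warning(sprintf("repaired %d dangling I- label(s) to B-", length(dangle)),
            call. = FALSE)
    kind[dangle] <- "B"
  }
  starts <- which(kind == "B")
  if (length(starts) == 0L) return(empty_annotations())
  out <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    s <- starts[j]; e <- s
    while (e < length(kind) && kind[e + 1L] == "I") e <- e + 1L
    out[[j]] <- data.frame(
      entity_type = entity_type,
      begin = tokens$begin[s], end = tokens$end[e],
      surface = paste(tokens$surface[s:e], collapse = " "),
      source = source, stringsAsFactors = FALSE)
  }
  spans <- do.call(rbind, out)
  # surfaces above assume single-space joining; recompute from offsets when a
  # raw text is attached to the tokens via attribute
  txt <- attr(tokens, "text")
  if (!is.null(txt)) spans$surface <- span_text(txt, spans$begin, spans$end)
  rownames(spans) <- NULL
  spans
}
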