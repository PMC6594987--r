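.TSV_COLS <- c("Begin", "End", "Word", "Lemma", "POS", "Chunk", "Dict", "GoldLabel")

#' Write sentences to token-per-line TSV
#'
#' CoNLL-style interchange: one token per line with the fixed,
#' tab-separated columns `Begin End Word Lemma POS Chunk Dict GoldLabel`;
#' a blank line separates sentences. The round trip through [read_tsv()] is
#' lossless.
#'
#' @param sentences List of data.frames, each with the eight columns (a
#'   featurized sentence, see [build_features()], plus labels).
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_tsv <- function(sentences, path = NULL) {
  blocks <- lapply(sentences, function(s) {
    stopifnot(all(.TSV_COLS %in% names(s)))
    do.call(sprintf, c(list("%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s"),
                       lapply(.TSV_COLS, function(cl) s[[cl]])))
  })
  lines <- character(0)
  for (i in seq_along(blocks)) {
    lines <- c(lines, blocks[[i]], if (i < length(blocks)) "")
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read token-per-line TSV into featurized sentences
#'
#' @param lines Character vector of lines, or a file path (single string
#'   naming an existing file).
#' @return List of sentence data.frames with columns
#'   `Begin End Word Lemma POS Chunk Dict GoldLabel`.
#' @export
read_tsv <- function(lines) {
  if (length(lines) == 1L && !grepl("\t", lines) && file.exists(lines)) {
    lines <- readLines(lines, encoding = "UTF-8", warn = FALSE)
  }
  sentences <- list()
  cur <- list()
  flush <- function() {
    if (length(cur) == 0L) return()
    df <- as.data.frame(do.call(rbind, cur), stringsAsFactors = FALSE)
    names(df) <- .TSV_COLS
    df$Begin <- as.integer(df$Begin)
    df$End <- as.integer(df$End)
    sentences[[length(sentences) + 1L]] <<- df
    cur <<- list()
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) { flush(); next }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(.TSV_COLS)) {
      stop(sprintf("row %d: expected %d tab-separated fields, got %d",
                   i, length(.TSV_COLS), length(fields)))
    }
    cur[[length(cur) + 1L]] <- fields
  }
  flush()
  sentences
}
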