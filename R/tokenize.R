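#' @useDynLib neuromine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif setNames
#' @importFrom utils head tail
NULL

# Punctuation detached from token edges. Hyphens are handled separately so
# that compounds ("Whole-cell") split *before* the hyphen and negative signs
# stay attached to their number.
.lead_punct  <- c("(", ")", "[", "]", "{", "}", "\"", "'", "“", "”",
                  "‘", "’", ":", ";", ",", "/")
.trail_punct <- c(.lead_punct, ".", "!", "?", "%")

#' Tokenize text with character offsets
#'
#' Rule-based tokenizer: splits on whitespace, detaches leading/trailing
#' punctuation (`:`, `(`, `)`, `,`, `;`, quotes, sentence-final `.?!`) as
#' standalone tokens, and splits hyphenated compounds before the hyphen, so
#' `"Whole-cell"` becomes `"Whole"`, `"-cell"`. Internal periods (decimals
#' such as `12.5`) and digit-adjacent hyphens (`10-20mv`) are left intact.
#'
#' Offsets are 0-based with an exclusive end, so `end - begin` equals the
#' surface length. Two conventions are supported: `"raw"` offsets index into
#' the original text (used by brat standoff output), while `"detokenized"`
#' offsets are computed over the token stream joined by single spaces, the
#' convention used in token-per-line feature tables.
#'
#' @param text Character scalar (UTF-8).
#' @param mode Offset convention, `"raw"` or `"detokenized"`.
#' @return A data.frame with columns `surface`, `begin`, `end`. Empty input
#'   yields a zero-row frame.
#' @examples
#' tokenize("Whole-cell recordings (VPM)")
#' @export
tokenize <- function(text, mode = c("raw", "detokenized")) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(surface = character(0), begin = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  # whitespace-delimited chunks with raw offsets
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  surfaces <- character(0); begins <- integer(0)

  push <- function(s, b) {
    surfaces[[length(surfaces) + 1L]] <<- s
    begins[[length(begins) + 1L]] <<- b
  }

  for (k in seq_along(starts)) {
    chunk <- substr(text, starts[k] + 1L, starts[k] + lens[k])
    base <- starts[k]
    chars <- strsplit(chunk, "", fixed = TRUE)[[1]]
    lo <- 1L; hi <- length(chars)
    lead <- character(0); trail <- character(0)
    while (lo < hi && chars[lo] %in% .lead_punct) { lead <- c(lead, chars[lo]); lo <- lo + 1L }
    while (hi > lo && chars[hi] %in% .trail_punct) { trail <- c(chars[hi], trail); hi <- hi - 1L }
    core <- paste(chars[lo:hi], collapse = "")
    if (hi == lo && core %in% .trail_punct && length(lead) == 0L && length(trail) == 0L) {
      push(core, base + lo - 1L)
      next
    }
    for (i in seq_along(lead)) push(lead[i], base + i - 1L)
    core_base <- base + lo - 1L
    # split compounds before an internal hyphen flanked by letter/alnum+letter
    pieces <- .split_hyphen(core)
    off <- 0L
    for (p in pieces) {
      push(p, core_base + off)
      off <- off + nchar(p)
    }
    for (i in seq_along(trail)) push(trail[i], base + hi + i - 1L)
  }

  ends <- begins + nchar(surfaces)
  out <- data.frame(surface = surfaces, begin = begins, end = ends,
                    stringsAsFactors = FALSE)
  if (mode == "detokenized") out <- .detok_offsets(out)
  out
}

# split "Whole-cell" -> c("Whole","-cell"); keep "10-20mv", "CaV3.1-/-" intact
.split_hyphen <- function(core) {
  n <- nchar(core)
  if (n < 3L) return(core)
  chars <- strsplit(core, "", fixed = TRUE)[[1]]
  cuts <- integer(0)
  for (i in 2:(n - 1L)) {
    if (chars[i] == "-" &&
        grepl("[[:alnum:]]", chars[i - 1L]) &&
        grepl("[[:alpha:]]", chars[i + 1L]) &&
        !grepl("[[:digit:]]", chars[i - 1L])) {
      cuts <- c(cuts, i)
    }
  }
  if (length(cuts) == 0L) return(core)
  bounds <- c(1L, cuts, n + 1L)
  vapply(seq_len(length(bounds) - 1L), function(j) {
    substr(core, bounds[j], bounds[j + 1L] - 1L)
  }, character(1))
}

.detok_offsets <- function(tokens) {
  if (nrow(tokens) == 0L) return(tokens)
  lens <- nchar(tokens$surface)
  begin <- cumsum(c(0L, head(lens, -1L) + 1L))
  tokens$begin <- as.integer(begin)
  tokens$end <- as.integer(begin + lens)
  tokens
}

#' Join token surfaces with single spaces
#'
#' @param tokens Token data.frame from [tokenize()].
#' @return Character scalar.
#' @export
detokenize <- function(tokens) paste(tokens$surface, collapse = " ")

.abbrev_guard <- c("e.g", "i.e", "al", "Fig", "Figs", "cf", "vs", "etc",
                   "approx", "ca", "no", "No", "Dr", "St", "Eq", "Eqs")

#' Split text into sentences
#'
#' Rule-based splitter: a sentence ends at `.`, `?` or `!` followed by
#' whitespace and an uppercase letter, digit or opening bracket, unless the
#' period terminates a known abbreviation (`e.g.`, `et al.`, `Fig.`, ...) or a
#' single capital initial.
#'
#' @param text Character scalar.
#' @return data.frame with 0-based `begin`, exclusive `end`, and `text` for
#'   each sentence.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(begin = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  n <- nchar(text)
  m <- gregexpr("[.?!]+(?=\\s+[\"'(\\[]?[A-Z0-9])", text, perl = TRUE)[[1]]
  cut_after <- integer(0)
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      pos <- as.integer(m[k]) + attr(m, "match.length")[k] - 1L  # 1-based last punct
      prev <- sub(".*?([A-Za-z.]+)$", "\\1", substr(text, max(1L, pos - 12L), pos - 1L))
      word <- sub("\\.$", "", prev)
      if (substr(text, pos, pos) == "." &&
          (word %in% .abbrev_guard || grepl("^[A-Z]$", word))) next
      cut_after <- c(cut_after, pos)
    }
  }
  bounds <- unique(c(0L, cut_after, n))
  out <- list()
  for (j in seq_len(length(bounds) - 1L)) {
    b <- bounds[j]; e <- bounds[j + 1L]
    seg <- substr(text, b + 1L, e)
    lead_ws <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail_ws <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    b2 <- b + lead_ws; e2 <- e - trail_ws
    if (e2 > b2) {
      out[[length(out) + 1L]] <- data.frame(
        begin = b2, end = e2, text = substr(text, b2 + 1L, e2),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Construct a document
#'
#' A document bundles an identifier, its full text, and sentence spans.
#'
#' @param doc_id Identifier string.
#' @param text Full document text.
#' @param sentences Optional sentence table; computed with
#'   [split_sentences()] when omitted.
#' @return An object of class `nm_document`.
#' @export
document <- function(doc_id, text, sentences = NULL) {
  if (is.null(sentences)) sentences <- split_sentences(text)
  stopifnot(all(sentences$begin >= 0), all(sentences$end <= nchar(text)))
  if (nrow(sentences) > 1L) {
    stopifnot(all(diff(sentences$begin) > 0),
              all(sentences$begin[-1L] >= head(sentences$end, -1L)))
  }
  structure(list(doc_id = doc_id, text = text, sentences = sentences),
            class = "nm_document")
}

#' @export
print.nm_document <- function(x, ...) {
  cat(sprintf("<nm_document '%s': %d chars, %d sentences>\n",
              x$doc_id, nchar(x$text), nrow(x$sentences)))
  invisible(x)
}

#' Extract covered text by 0-based, end-exclusive offsets
#'
#' @param text Character scalar.
#' @param begin,end Integer offsets (0-based begin, exclusive end).
#' @return Character vector of covered substrings.
#' @export
span_text <- function(text, begin, end) {
  substring(text, begin + 1L, end)
}
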