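# Bundled POS tagger, lemmatizer and NP chunker.
#
# The feature schema only requires *a* POS/chunk provider honouring the
# B-/I-/O chunk-column contract; this one is a small lexicon plus suffix
# rules, which keeps the package dependency-light and fully offline.

.pos_env <- new.env(parent = emptyenv())

.pos_lexicon <- function() {
  if (is.null(.pos_env$lex)) {
    path <- system.file("extdata", "pos_lexicon.tsv", package = "neuromine")
    raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
    raw <- raw[nzchar(raw)]
    parts <- strsplit(raw, "\t", fixed = TRUE)
    words <- vapply(parts, `[`, character(1), 1L)
    pos <- vapply(parts, `[`, character(1), 2L)
    lemma <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_,
                    character(1))
    .pos_env$lex <- list(pos = setNames(pos, words),
                         lemma = setNames(lemma, words))
  }
  .pos_env$lex
}

.PUNCT_POS <- c(":" = ":", ";" = ":", "," = ",", "." = ".", "!" = ".",
                "?" = ".", "(" = "(", ")" = ")", "[" = "(", "]" = ")",
                "\"" = "''", "'" = "''", "/" = ":", "%" = "NN")

#' Part-of-speech tag a token sequence
#'
#' Lexicon lookup (case-insensitive) with suffix-rule fallback: numbers
#' become `CD`, `-ly` adverbs `RB`, `-ing`/`-ed` verb forms, plural nouns
#' `NNS`, everything else `NN`. The collocations "in vivo"/"in vitro"/"in
#' situ" are tagged `FW FW` as foreign phrases.
#'
#' @param surfaces Character vector of token surfaces.
#' @return Character vector of Penn-style POS tags.
#' @export
pos_tag <- function(surfaces) {
  lex <- .pos_lexicon()$pos
  n <- length(surfaces)
  tags <- character(n)
  lower <- tolower(surfaces)
  for (i in seq_len(n)) {
    s <- surfaces[i]
    if (s %in% names(.PUNCT_POS)) { tags[i] <- .PUNCT_POS[[s]]; next }
    if (grepl("^[−-]?\\d+(,\\d{3})*(\\.\\d+)?$", s)) { tags[i] <- "CD"; next }
    if (startsWith(s, "-")) { tags[i] <- "JJ"; next }  # hyphen-led compound part
    hit <- lex[lower[i]]
    if (!is.na(hit)) { tags[i] <- hit; next }
    w <- lower[i]
    tags[i] <-
      if (grepl("ly$", w)) "RB"
      else if (grepl("ed$", w) && nchar(w) > 3L) "VBD"
      else if (grepl("ing$", w) && nchar(w) > 4L) "VBG"
      else if (grepl("[a-z]s$", w) && !grepl("(ss|us|is)$", w) && nchar(w) > 3L) "NNS"
      else "NN"
  }
  # foreign-phrase collocations: "in vivo", "in vitro", "in situ"
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (lower[i] == "in" && lower[i + 1L] %in% c("vivo", "vitro", "situ")) {
        tags[i] <- "FW"; tags[i + 1L] <- "FW"
      }
    }
  }
  tags
}

#' Lemmatize tokens by dictionary lookup
#'
#' Irregular forms come from the bundled lexicon (`were` -> `be`, `made` ->
#' `make`); regular plurals are stripped (`recordings` -> `recording`);
#' everything else falls back to the identity, preserving case.
#'
#' @param surfaces Token surfaces.
#' @param pos Matching POS tags (from [pos_tag()]).
#' @return Character vector of lemmas.
#' @export
lemmatize <- function(surfaces, pos = pos_tag(surfaces)) {
  lex <- .pos_lexicon()$lemma
  lower <- tolower(surfaces)
  out <- surfaces
  for (i in seq_along(surfaces)) {
    hit <- lex[lower[i]]
    if (!is.na(hit)) { out[i] <- hit; next }
    if (pos[i] == "NNS") {
      w <- surfaces[i]
      out[i] <-
        if (grepl("ies$", w)) sub("ies$", "y", w)
        else if (grepl("[a-z]s$", w)) sub("s$", "", w)
        else w
    }
  }
  out
}

#' Shallow chunk tags over a POS sequence
#'
#' Regex-over-POS chunker producing B-/I-/O tags for noun phrases (optional
#' determiner followed by adjectives, numbers, nouns and foreign words), verb
#' phrases (verb runs), prepositional phrases (`IN`), and adverb phrases
#' (adverbs and the `in vivo`-style FW collocations). Punctuation is `O`.
#' Number lists ("15, 30 and 45") stay inside one noun phrase so that a
#' trailing unit shares the phrase with every listed value.
#'
#' @param surfaces Token surfaces.
#' @param pos POS tags from [pos_tag()].
#' @return Character vector of chunk tags.
#' @export
chunk_tags <- function(surfaces, pos = pos_tag(surfaces)) {
  n <- length(surfaces)
  if (n == 0L) return(character(0))
  lower <- tolower(surfaces)
  fw_advp <- rep(FALSE, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (lower[i] == "in" && lower[i + 1L] %in% c("vivo", "vitro", "situ")) {
        fw_advp[i] <- TRUE; fw_advp[i + 1L] <- TRUE
      }
    }
  }
  np_pos <- c("DT", "JJ", "JJR", "JJS", "CD", "NN", "NNS", "NNP", "FW",
              "PRP$", "VBG")
  vp_pos <- c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ", "MD", "TO")
  chunks <- character(n)
  phrase <- "O"  # phrase type of previous token
  for (i in seq_len(n)) {
    p <- pos[i]
    this <-
      if (fw_advp[i]) "ADVP"
      else if (p %in% c(":", ",", ".", "(", ")", "''")) "O"
      else if (p %in% vp_pos && !(p == "VBG" && phrase == "NP")) "VP"
      else if (p == "IN") "PP"
      else if (p %in% c("RB", "RBR", "RBS")) "ADVP"
      else if (p %in% np_pos) "NP"
      else if (p %in% c("CC", "WDT", "WRB", "PRP")) "O"
      else "NP"
    # keep coordinated number lists in one NP: ", 30" / "and 45"
    if (this == "O" && phrase == "NP" && (p %in% c(",", "CC")) &&
        i < n && pos[i + 1L] == "CD") {
      this <- "NP"
      chunks[i] <- "I-NP"; phrase <- "NP"; next
    }
    if (this == "O") {
      chunks[i] <- "O"
    } else if (phrase == this && !(this == "NP" && p == "DT")) {
      chunks[i] <- paste0("I-", this)
    } else {
      chunks[i] <- paste0("B-", this)
    }
    phrase <- this
  }
  chunks
}

#' Extract noun phrases from chunk tags
#'
#' Maximal `B-NP I-NP*` runs become noun phrases.
#'
#' @param tokens Token data.frame.
#' @param chunks Chunk tags from [chunk_tags()].
#' @return data.frame with `begin`, `end` (character offsets), `first`,
#'   `last` (token indices) and `text` (space-joined surfaces).
#' @export
noun_phrases <- function(tokens, chunks = chunk_tags(tokens$surface)) {
  stopifnot(length(chunks) == nrow(tokens))
  out <- list()
  i <- 1L
  while (i <= length(chunks)) {
    if (chunks[i] == "B-NP") {
      j <- i
      while (j < length(chunks) && chunks[j + 1L] == "I-NP") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        begin = tokens$begin[i], end = tokens$end[j], first = i, last = j,
        text = paste(tokens$surface[i:j], collapse = " "),
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0L) {
    return(data.frame(begin = integer(0), end = integer(0), first = integer(0),
                      last = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
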