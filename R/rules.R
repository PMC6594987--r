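# Deterministic rule-based annotator: numeric value detection, noun-phrase
# scoped entity regexes, value-unit linking and acronym propagation.

.VALUE_REGEX <- "\\d+(,\\d{3})*(\\.\\d+)?"

.NP_PATTERNS <- c(
  NeuronType = "\\b(neurone?s?|cells?)\\b",
  IonCurrent = "\\b(current)s?\\b",
  IonChannel = "\\b(channel)s?\\b",
  IonConductance = "\\b(conductance)s?\\b")

#' Detect numeric values in text
#'
#' Matches well-formed integers, thousands-grouped integers ("23,400,500")
#' and decimals ("12.5") as single spans. Candidates embedded in malformed
#' decimal or thousands context are rejected, so "1.1.1.1" yields nothing.
#' A directly preceding minus sign (ASCII `-` or Unicode `−`, with at most
#' one intervening space) is absorbed in post-processing, unless the token
#' before the sign is itself a number — which keeps ranges written as
#' "10-20" from turning the 20 negative.
#'
#' @param text Character scalar.
#' @param absorb_negative Absorb preceding minus signs (default `TRUE`).
#' @return data.frame with `begin`, `end`, `surface` and the parsed `value`.
#' @export
detect_values <- function(text, absorb_negative = TRUE) {
  empty <- data.frame(begin = integer(0), end = integer(0),
                      surface = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr(.VALUE_REGEX, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  out <- list()
  for (k in seq_along(m)) {
    b <- as.integer(m[k]) - 1L
    e <- b + attr(m, "match.length")[k]
    before <- if (b > 0L) substr(text, b - 1L + ifelse(b > 1L, 0L, 1L), b) else ""
    before2 <- if (b >= 2L) substr(text, b - 1L, b) else ""
    after2 <- substr(text, e + 1L, e + 2L)
    # reject candidates flanked by a digit-adjacent '.' or ',' (e.g. 1.1.1.1)
    if (grepl("^[.,][0-9]", after2)) next
    if (grepl("^[0-9][.,]$", before2)) next
    surface <- span_text(text, b, e)
    if (absorb_negative) {
      pre <- substr(text, max(1L, b - 2L), b)
      sign_m <- regexpr("[−-] ?$", pre, perl = TRUE)
      if (sign_m[1] != -1L) {
        sign_len <- attr(sign_m, "match.length")
        sb <- b - sign_len
        # list-context guard: do not absorb when a number directly precedes
        lead <- substr(text, 1L, sb)
        if (!grepl("[0-9] ?$", lead)) {
          b <- sb
          surface <- span_text(text, b, e)
        }
      }
    }
    value <- as.numeric(gsub(",", "", sub("^[−-] ?", "-", surface)))
    out[[length(out) + 1L]] <- data.frame(
      begin = b, end = e, surface = surface, value = value,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Noun-phrase scoped entity regex matching
#'
#' Evaluates each noun phrase against the per-type patterns (neuron(e)s /
#' cell(s), current(s), channel(s), conductance(s)); when a phrase contains
#' a match, the whole noun phrase becomes one span of the matched type.
#'
#' @param nps Noun-phrase table from [noun_phrases()].
#' @param entity_type One of NeuronType, IonCurrent, IonChannel,
#'   IonConductance; or `"all"` for every pattern.
#' @param text Optional raw text for exact surfaces.
#' @return Span annotation table with `source = "regex"`.
#' @export
regex_np_match <- function(nps, entity_type = "all", text = NULL) {
  types <- if (identical(entity_type, "all")) names(.NP_PATTERNS)
  else {
    if (!entity_type %in% names(.NP_PATTERNS)) {
      stop("no noun-phrase pattern for entity type '", entity_type, "'")
    }
    entity_type
  }
  out <- empty_annotations()
  if (nrow(nps) == 0L) return(out)
  for (ty in types) {
    hit <- grepl(.NP_PATTERNS[[ty]], nps$text, ignore.case = TRUE, perl = TRUE)
    if (!any(hit)) next
    surf <- if (!is.null(text)) span_text(text, nps$begin[hit], nps$end[hit])
    else nps$text[hit]
    out <- .bind_annotations(out, data.frame(
      entity_type = ty, begin = nps$begin[hit], end = nps$end[hit],
      surface = surf, source = "regex", stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Link detected values to units within noun phrases
#'
#' A value is linked to a unit when both fall inside the same noun phrase,
#' which covers ranges and lists where the unit appears only at the end
#' ("10-20mv", "15, 30 and 45 millimetres"). Every linked value becomes an
#' `ExperimentalValue`; when the unit directly follows the value the span is
#' extended to include it ("12.5 microM"). Values with no unit in their
#' phrase are still emitted, without extension. Sample sizes ("n = 12") are
#' excluded.
#'
#' @param values From [detect_values()].
#' @param units Unit spans from [match_units()].
#' @param nps Noun phrases from [noun_phrases()].
#' @param text Raw text.
#' @return List with `annotations` (ExperimentalValue spans) and `links`
#'   (data.frame value index, unit index, numeric value, unit surface).
#' @export
link_value_unit <- function(values, units, nps, text) {
  ann <- empty_annotations()
  links <- data.frame(value = integer(0), unit = integer(0),
                      value_num = numeric(0), unit_surface = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(values) == 0L) return(list(annotations = ann, links = links))

  np_of <- function(b, e) {
    hit <- which(nps$begin <= b & nps$end >= e)
    if (length(hit)) hit[1L] else NA_integer_
  }
  keep <- !vapply(seq_len(nrow(values)), function(i) {
    .is_sample_size(text, values$begin[i])
  }, logical(1))
  values <- values[keep, , drop = FALSE]
  if (nrow(values) == 0L) return(list(annotations = ann, links = links))

  v_np <- mapply(np_of, values$begin, values$end)
  u_np <- if (nrow(units)) mapply(np_of, units$begin, units$end) else integer(0)

  rows <- list()
  for (i in seq_len(nrow(values))) {
    b <- values$begin[i]; e <- values$end[i]
    u_idx <- NA_integer_
    if (!is.na(v_np[i]) && length(u_np)) {
      same <- which(u_np == v_np[i])
      if (length(same)) {
        # nearest unit at or after the value, else nearest before
        after <- same[units$begin[same] >= e]
        u_idx <- if (length(after)) after[which.min(units$begin[after])]
        else same[which.max(units$begin[same])]
      }
    }
    if (!is.na(u_idx)) {
      gap <- span_text(text, e, units$begin[u_idx])
      if (units$begin[u_idx] >= e && grepl("^ ?$", gap)) e <- units$end[u_idx]
      links <- rbind(links, data.frame(
        value = i, unit = u_idx, value_num = values$value[i],
        unit_surface = units$surface[u_idx], stringsAsFactors = FALSE))
    } else {
      links <- rbind(links, data.frame(
        value = i, unit = NA_integer_, value_num = values$value[i],
        unit_surface = NA_character_, stringsAsFactors = FALSE))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      entity_type = "ExperimentalValue", begin = b, end = e,
      surface = span_text(text, b, e), source = "regex",
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  list(annotations = ann, links = links)
}

# "n = 12" / "N=12" sample sizes are not experimental values
.is_sample_size <- function(text, begin) {
  pre <- substr(text, max(1L, begin - 5L), begin)
  grepl("\\b[nN] ?= ?$", pre)
}

#' Detect parenthetical abbreviations
#'
#' Finds "LONG FORM (SF)" patterns: a short form of 2-10 characters with at
#' least one uppercase letter inside parentheses, validated against the
#' preceding words by in-order character overlap. The long form is the
#' shortest preceding word span whose first word starts with the short
#' form's first letter and which contains all but at most one of the short
#' form's letters in order.
#'
#' @param text Document text.
#' @return data.frame with `long_begin`, `long_end`, `long_form`,
#'   `short_form`, `sf_begin`, `sf_end`.
#' @export
find_abbreviations <- function(text) {
  empty <- data.frame(long_begin = integer(0), long_end = integer(0),
                      long_form = character(0), short_form = character(0),
                      sf_begin = integer(0), sf_end = integer(0),
                      stringsAsFactors = FALSE)
  if (!grepl("(", text, fixed = TRUE)) return(empty)
  m <- gregexpr("\\(([^()\\s]{2,10})\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  toks <- tokenize(text)
  out <- list()
  for (k in seq_along(m)) {
    open <- as.integer(m[k]) - 1L                 # offset of '('
    len <- attr(m, "match.length")[k]
    sf <- substr(text, open + 2L, open + len - 1L)
    if (!grepl("[A-Z]", sf)) next
    letters_sf <- strsplit(gsub("[^A-Za-z]", "", sf), "")[[1]]
    if (length(letters_sf) < 2L) next
    # words strictly before '(' (skip detached punctuation)
    before <- which(toks$end <= open & grepl("[[:alnum:]]", toks$surface))
    if (length(before) == 0L) next
    max_words <- min(length(letters_sf) + 5L, 2L * length(letters_sf), length(before))
    found <- NULL
    for (nw in seq_len(max_words)) {  # shortest span first
      idx <- tail(before, nw)
      span_words <- toks$surface[idx]
      if (tolower(substr(span_words[1L], 1L, 1L)) != tolower(letters_sf[1L])) next
      lf <- paste(span_words, collapse = " ")
      if (.char_overlap(letters_sf, lf) >= length(letters_sf) - 1L) {
        found <- idx
        break
      }
    }
    if (is.null(found)) next
    b <- toks$begin[found[1L]]; e <- toks$end[found[length(found)]]
    out[[length(out) + 1L]] <- data.frame(
      long_begin = b, long_end = e, long_form = span_text(text, b, e),
      short_form = sf, sf_begin = open + 1L, sf_end = open + 1L + nchar(sf),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# count of `letters` (in order, case-insensitive) present in `s`
.char_overlap <- function(letters_sf, s) {
  sc <- strsplit(tolower(s), "")[[1]]
  i <- 1L; matched <- 0L
  for (ch in tolower(letters_sf)) {
    while (i <= length(sc) && sc[i] != ch) i <- i + 1L
    if (i <= length(sc)) { matched <- matched + 1L; i <- i + 1L }
  }
  matched
}

#' Propagate annotation types to acronym mentions
#'
#' If an abbreviation's expanded form carries an entity annotation anywhere
#' in the document, every standalone occurrence of the short form receives
#' the same type (source `"acronym"`). Existing spans are never duplicated.
#'
#' @param text Document text.
#' @param annotations Current annotation table.
#' @param abbreviations From [find_abbreviations()].
#' @return Augmented annotation table.
#' @export
propagate_acronyms <- function(text, annotations, abbreviations) {
  if (nrow(abbreviations) == 0L || nrow(annotations) == 0L) return(annotations)
  extra <- list()
  for (k in seq_len(nrow(abbreviations))) {
    lf <- abbreviations$long_form[k]
    sf <- abbreviations$short_form[k]
    carriers <- annotations[tolower(annotations$surface) == tolower(lf), , drop = FALSE]
    if (nrow(carriers) == 0L) next
    for (ty in unique(carriers$entity_type)) {
      pat <- paste0("(?<![[:alnum:]])", .regex_escape(sf), "(?![[:alnum:]])")
      m <- gregexpr(pat, text, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (j in seq_along(m)) {
        b <- as.integer(m[j]) - 1L
        e <- b + attr(m, "match.length")[j]
        extra[[length(extra) + 1L]] <- data.frame(
          entity_type = ty, begin = b, end = e, surface = sf,
          source = "acronym", stringsAsFactors = FALSE)
      }
    }
  }
  .dedup_annotations(.bind_annotations(annotations, do.call(rbind, extra)))
}

#' Run the full rule and dictionary annotator over a document
#'
#' Composes, per document: dictionary longest-match for the six
#' dictionary-backed types, noun-phrase regex matching, unit gazetteer
#' matching, numeric value detection with value-unit linking, and
#' document-level acronym propagation.
#'
#' @param doc An `nm_document` (or character text).
#' @param types Entity types to annotate (default all eight).
#' @param dictionaries Named list of dictionary entry vectors; bundled
#'   dictionaries are loaded for any type not supplied.
#' @return Span annotation table in raw text offsets.
#' @export
annotate_rules <- function(doc, types = ENTITY_TYPES, dictionaries = list()) {
  if (is.character(doc)) doc <- document("doc", doc)
  text <- doc$text
  toks <- tokenize(text)
  pos <- pos_tag(toks$surface)
  chunks <- chunk_tags(toks$surface, pos)
  nps <- noun_phrases(toks, chunks)

  ann <- empty_annotations()
  for (ty in intersect(types, names(.DICT_FILES))) {
    dict <- dictionaries[[ty]]
    if (is.null(dict)) dict <- load_dictionary(ty)
    ann <- .bind_annotations(ann, dict_match(toks, dict, ty, text = text))
  }
  regex_types <- intersect(types, names(.NP_PATTERNS))
  for (ty in regex_types) {
    ann <- .bind_annotations(ann, regex_np_match(nps, ty, text = text))
  }
  units <- if ("Unit" %in% types || "ExperimentalValue" %in% types) {
    match_units(text)
  } else empty_annotations()
  if ("Unit" %in% types) ann <- .bind_annotations(ann, units)
  if ("ExperimentalValue" %in% types) {
    values <- detect_values(text)
    linked <- link_value_unit(values, units, nps, text)
    ann <- .bind_annotations(ann, linked$annotations)
  }
  abbr <- find_abbreviations(text)
  ann <- propagate_acronyms(text, ann, abbr)
  ann <- .dedup_annotations(ann)
  ann[order(ann$begin, ann$end, ann$entity_type), , drop = FALSE]
}
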