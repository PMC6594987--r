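# Entity dictionaries and the scientific-unit gazetteer.
#
# Dictionary files are UTF-8, one entry per line, optionally with extra
# tab-separated synonym columns; every column becomes an entry. The bundled
# snapshots are small curated lists; they are reconstructions assembled from
# SI conventions and standard neuroscience nomenclature, not a download.

.DICT_FILES <- c(BrainRegion = "dict_brainregion.tsv",
                 NeuronType = "dict_neurontype.tsv",
                 ModelOrganism = "dict_modelorganism.tsv",
                 IonChannel = "dict_ionchannel.tsv",
                 IonCurrent = "dict_ioncurrent.tsv",
                 IonConductance = "dict_ionconductance.tsv")

#' Load an entity dictionary
#'
#' @param entity_type One of the six dictionary-backed entity types, or a
#'   file path to a dictionary in the one-entry-per-line dialect.
#' @return Character vector of unique, non-empty entries.
#' @export
load_dictionary <- function(entity_type) {
  path <- if (file.exists(entity_type)) entity_type
  else {
    if (!entity_type %in% names(.DICT_FILES)) {
      stop("no bundled dictionary for entity type '", entity_type, "'")
    }
    system.file("extdata", .DICT_FILES[[entity_type]], package = "neuromine")
  }
  if (!nzchar(path)) stop("dictionary file not found for '", entity_type, "'")
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- unlist(strsplit(raw[nzchar(raw)], "\t", fixed = TRUE))
  entries <- unique(trimws(entries))
  entries[nzchar(entries)]
}

#' Derive an ion-conductance dictionary from an ion-current dictionary
#'
#' Applies the naming correspondence between currents and the conductances
#' that generate them: the word "current(s)" is rewritten to
#' "conductance(s)", and acronyms with a leading `I` (e.g. `IH`, `I(Ts)`)
#' have it replaced by `g` (`gH`, `g(Ts)`).
#'
#' @param current_entries Character vector of ion-current dictionary entries.
#' @return Character vector of conductance entries (deduplicated, in order).
#' @export
derive_conductance_dictionary <- function(current_entries) {
  out <- vapply(current_entries, function(e) {
    if (grepl("currents?", e, ignore.case = TRUE)) {
      e <- sub("currents", "conductances", e, ignore.case = TRUE)
      sub("current", "conductance", e, ignore.case = TRUE)
    } else if (grepl("^I[^a-z]", e) || grepl("^I\\(", e)) {
      sub("^I", "g", e)
    } else if (grepl("^I[a-z]", e) && nchar(e) <= 5L) {
      sub("^I", "g", e)
    } else e
  }, character(1), USE.NAMES = FALSE)
  unique(out)
}

# ---- unit gazetteer ---------------------------------------------------------

.read_forms <- function(file) {
  path <- system.file("extdata", file, package = "neuromine")
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw <- raw[nzchar(raw)]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop(sprintf("malformed gazetteer line %d in %s", bad[1], file))
  list(long = vapply(parts, `[`, character(1), 1L),
       short = vapply(parts, `[`, character(1), 2L),
       alts = lapply(parts, function(p) if (length(p) > 2L) p[-(1:2)] else character(0)))
}

#' Load the scientific-unit gazetteer
#'
#' The gazetteer holds 24 base unit names (volt, gram, metre, ...) with their
#' short forms, and 19 standard prefixes (milli, kilo, micro, ...) with
#' theirs; a handful of bases/prefixes also carry alternate short spellings.
#'
#' @return List with data.frames `bases` and `prefixes` (`long`, `short`,
#'   `alts`).
#' @export
unit_gazetteer <- function() {
  b <- .read_forms("units_base.tsv")
  p <- .read_forms("units_prefix.tsv")
  list(bases = b, prefixes = p)
}

#' Expand the unit gazetteer into matchable surface forms
#'
#' Every prefix-base combination is generated in long form ("milligram",
#' "kilometre") and short form ("mg", "km", "mm"), plus bare bases ("volt",
#' "g") and mixed long-prefix + short-base forms ("microM"). Long forms are
#' matched case-insensitively (with optional plural); forms containing a
#' short component are matched case-sensitively, so "mV" is distinct from
#' "MV".
#'
#' @param gazetteer From [unit_gazetteer()].
#' @return data.frame with `form`, `kind` (`long`/`short`/`mixed`) and
#'   `case_sensitive`.
#' @export
expand_unit_gazetteer <- function(gazetteer = unit_gazetteer()) {
  b <- gazetteer$bases; p <- gazetteer$prefixes
  long_pref <- c("", p$long)
  long <- as.vector(outer(long_pref, b$long, paste0))
  short_pref <- c("", unlist(Map(c, p$short, p$alts)))
  base_short <- unlist(Map(c, b$short, b$alts))
  short <- as.vector(outer(unique(short_pref), unique(base_short), paste0))
  mixed <- as.vector(outer(p$long, unique(base_short), paste0))
  out <- rbind(
    data.frame(form = long, kind = "long", case_sensitive = FALSE,
               stringsAsFactors = FALSE),
    data.frame(form = short, kind = "short", case_sensitive = TRUE,
               stringsAsFactors = FALSE),
    data.frame(form = mixed, kind = "mixed", case_sensitive = TRUE,
               stringsAsFactors = FALSE))
  out <- out[!duplicated(paste(out$form, out$case_sensitive)), ]
  rownames(out) <- NULL
  out
}

#' Find unit mentions in text
#'
#' Scans the raw text for gazetteer forms bounded by non-letters, so units
#' fused to a number ("20mv") are still found. Long forms allow a plural
#' "(e)s"; short and mixed forms are matched case-sensitively. Overlapping
#' candidates resolve leftmost-longest.
#'
#' @param text Character scalar.
#' @param forms Expansion from [expand_unit_gazetteer()].
#' @return Span annotation table with `entity_type = "Unit"`.
#' @export
match_units <- function(text, forms = expand_unit_gazetteer()) {
  if (!nzchar(text)) return(empty_annotations())
  hits <- list()
  scan <- function(form_set, ignore_case, plural) {
    if (length(form_set) == 0L) return()
    form_set <- form_set[order(-nchar(form_set))]
    pat <- paste0("(?<![A-Za-zµΩ])(?:",
                  paste(vapply(form_set, .regex_escape, character(1)),
                        collapse = "|"),
                  ")", if (plural) "(?:e?s)?", "(?![A-Za-zµΩ])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = ignore_case)[[1]]
    if (m[1] == -1L) return()
    for (k in seq_along(m)) {
      b <- as.integer(m[k]) - 1L
      e <- b + attr(m, "match.length")[k]
      hits[[length(hits) + 1L]] <<- c(b, e)
    }
  }
  scan(forms$form[!forms$case_sensitive], ignore_case = TRUE, plural = TRUE)
  scan(forms$form[forms$case_sensitive], ignore_case = FALSE, plural = FALSE)
  if (length(hits) == 0L) return(empty_annotations())
  h <- do.call(rbind, hits)
  h <- h[order(h[, 1], -(h[, 2] - h[, 1])), , drop = FALSE]
  keep <- list(); last_end <- -1L
  for (i in seq_len(nrow(h))) {
    if (h[i, 1] >= last_end) { keep[[length(keep) + 1L]] <- h[i, ]; last_end <- h[i, 2] }
  }
  k <- do.call(rbind, keep)
  span_annotation("Unit", k[, 1], k[, 2], span_text(text, k[, 1], k[, 2]),
                  source = "dictionary")
}

.regex_escape <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

# ---- dictionary longest match ----------------------------------------------

#' Dictionary matching over a token sequence
#'
#' Leftmost-longest, non-overlapping matching of dictionary entries against
#' the token stream. Entries are compared token-by-token after running them
#' through the same tokenizer as the text. Entries longer than three
#' characters match case-insensitively; entries of three characters or fewer
#' (acronyms such as "VPM") match case-sensitively, which avoids false hits
#' on common short words.
#'
#' @param tokens Token data.frame for one sentence or document.
#' @param dictionary Character vector of entries (see [load_dictionary()]).
#' @param entity_type Type recorded on emitted spans.
#' @param text Optional raw text used to recover exact surfaces.
#' @return Span annotation table with `source = "dictionary"`.
#' @export
dict_match <- function(tokens, dictionary, entity_type, text = NULL) {
  if (length(dictionary) == 0L || nrow(tokens) == 0L) return(empty_annotations())
  entry_toks <- lapply(dictionary, function(e) tokenize(e)$surface)
  keep <- lengths(entry_toks) > 0L
  entry_toks <- entry_toks[keep]
  entries <- dictionary[keep]
  case_sens <- nchar(entries) <= 3L
  first_key <- vapply(entry_toks, function(t) tolower(t[1L]), character(1))
  index <- split(seq_along(entries), first_key)

  surf <- tokens$surface
  lower <- tolower(surf)
  n <- length(surf)
  out <- list()
  i <- 1L
  while (i <= n) {
    cands <- index[[lower[i]]]
    best_len <- 0L; best_j <- NA_integer_
    for (j in cands) {
      et <- entry_toks[[j]]
      L <- length(et)
      if (L <= best_len || i + L - 1L > n) next
      seg <- surf[i:(i + L - 1L)]
      ok <- if (case_sens[j]) identical(seg, et)
      else identical(tolower(seg), tolower(et))
      if (ok) { best_len <- L; best_j <- j }
    }
    if (best_len > 0L) {
      b <- tokens$begin[i]; e <- tokens$end[i + best_len - 1L]
      surface <- if (!is.null(text)) span_text(text, b, e)
      else paste(surf[i:(i + best_len - 1L)], collapse = " ")
      out[[length(out) + 1L]] <- data.frame(
        entity_type = entity_type, begin = b, end = e, surface = surface,
        source = "dictionary", stringsAsFactors = FALSE)
      i <- i + best_len
    } else i <- i + 1L
  }
  if (length(out) == 0L) return(empty_annotations())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
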