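#' Read a brat standoff document
#'
#' Parses the text-bound (`T`) lines of a brat `.ann` file against its `.txt`
#' content: `Tn<TAB>Type begin end<TAB>surface`. Offsets are 0-based with an
#' exclusive end. Overlapping annotations of different types are preserved.
#' Non-`T` lines (relations, events, notes) are skipped with a warning.
#'
#' @param txt_content Document text (character scalar), or a path via
#'   `read_brat_files()`.
#' @param ann_content Character vector of `.ann` lines, or a single string
#'   with embedded newlines.
#' @param doc_id Identifier for the resulting document.
#' @param unknown_type `"error"` or `"skip"` (skip with warning) for entity
#'   types outside [ENTITY_TYPES].
#' @return List with elements `document` (class `nm_document`) and
#'   `annotations` (span table, `source = "gold"`).
#' @export
read_brat <- function(txt_content, ann_content, doc_id = "doc",
                      unknown_type = c("skip", "error")) {
  unknown_type <- match.arg(unknown_type)
  stopifnot(is.character(txt_content), length(txt_content) == 1L)
  if (length(ann_content) == 1L && grepl("\n", ann_content)) {
    ann_content <- strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  }
  ann_content <- ann_content[nzchar(trimws(ann_content))]
  doc <- document(doc_id, txt_content)
  rows <- list()
  for (i in seq_along(ann_content)) {
    line <- ann_content[i]
    if (!startsWith(line, "T")) {
      warning(sprintf("line %d: ignoring non-T brat line '%s'", i,
                      substr(line, 1, 20)), call. = FALSE)
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop(sprintf("line %d: malformed T-line", i))
    mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (length(mid) != 3L) {
      if (length(mid) > 3L && any(grepl(";", mid, fixed = TRUE))) {
        stop(sprintf("line %d: discontinuous (;) spans are not supported", i))
      }
      stop(sprintf("line %d: expected 'Type begin end'", i))
    }
    type <- mid[1]
    b <- suppressWarnings(as.integer(mid[2]))
    e <- suppressWarnings(as.integer(mid[3]))
    if (is.na(b) || is.na(e)) stop(sprintf("line %d: non-integer offsets", i))
    if (!type %in% ENTITY_TYPES) {
      msg <- sprintf("line %d: unknown entity type '%s'", i, type)
      if (unknown_type == "error") stop(msg)
      warning(msg, call. = FALSE)
      next
    }
    covered <- span_text(txt_content, b, e)
    if (!identical(covered, parts[3])) {
      stop(sprintf("line %d: surface mismatch at [%d,%d): file has '%s', text has '%s'",
                   i, b, e, parts[3], covered))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      entity_type = type, begin = b, end = e, surface = covered,
      source = "gold", stringsAsFactors = FALSE)
  }
  ann <- if (length(rows)) do.call(rbind, rows) else empty_annotations()
  rownames(ann) <- NULL
  list(document = doc, annotations = ann)
}

#' Write annotations as brat standoff lines
#'
#' Inverse of [read_brat()]: emits one `T` line per annotation, numbered in
#' row order.
#'
#' @param annotations Span annotation table with offsets into the raw text.
#' @return Character vector of `.ann` lines (zero-length for no annotations).
#' @export
write_brat <- function(annotations) {
  if (nrow(annotations) == 0L) return(character(0))
  sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(annotations)),
          annotations$entity_type, annotations$begin, annotations$end,
          annotations$surface)
}

#' Read or write brat document pairs on disk
#'
#' @param txt_path,ann_path File paths of the `.txt` / `.ann` pair.
#' @param ... Passed to [read_brat()].
#' @return As [read_brat()].
#' @export
read_brat_files <- function(txt_path, ann_path, ...) {
  txt <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  ann <- if (file.exists(ann_path)) {
    readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  } else character(0)
  read_brat(txt, ann, doc_id = sub("\\.txt$", "", basename(txt_path)), ...)
}

#' @rdname read_brat_files
#' @param document `nm_document` to write.
#' @param annotations Span table to write.
#' @export
write_brat_files <- function(document, annotations, txt_path, ann_path) {
  writeLines(document$text, txt_path, useBytes = TRUE)
  writeLines(write_brat(annotations), ann_path, useBytes = TRUE)
  invisible(c(txt_path, ann_path))
}
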