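#' The eight entity types of the annotation scheme
#'
#' Brain regions, neuron types, model organisms, ion channels, ion currents,
#' ion conductances, experimental values, and units.
#'
#' @export
ENTITY_TYPES <- c("BrainRegion", "NeuronType", "ModelOrganism", "IonChannel",
                  "IonCurrent", "IonConductance", "ExperimentalValue", "Unit")

.ANNOTATION_SOURCES <- c("gold", "dictionary", "regex", "crf", "neural", "acronym")

#' Construct a span annotation table
#'
#' A span annotation is a typed character-offset entity mention: 0-based
#' begin, exclusive end, the covered surface text, and a provenance source.
#' Vectorized over all arguments.
#'
#' @param entity_type One of [ENTITY_TYPES].
#' @param begin,end Character offsets, `begin < end`.
#' @param surface Covered text; must equal the document text at the offsets
#'   (validated where the caller has the text, see [read_brat()]).
#' @param source Provenance: gold, dictionary, regex, crf, neural or acronym.
#' @return data.frame with columns `entity_type`, `begin`, `end`, `surface`,
#'   `source`.
#' @export
span_annotation <- function(entity_type, begin, end, surface, source = "gold") {
  n <- max(length(entity_type), length(begin), length(end), length(surface))
  if (n == 0L) return(empty_annotations())
  out <- data.frame(entity_type = rep_len(as.character(entity_type), n),
                    begin = rep_len(as.integer(begin), n),
                    end = rep_len(as.integer(end), n),
                    surface = rep_len(as.character(surface), n),
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$entity_type), ENTITY_TYPES)
  if (length(bad)) stop("unknown entity type(s): ", paste(bad, collapse = ", "))
  if (any(out$begin >= out$end)) stop("span annotations need begin < end")
  if (any(nchar(out$surface) != out$end - out$begin)) {
    stop("surface length must equal end - begin")
  }
  out
}

#' Zero-row annotation table
#' @return data.frame with the span-annotation columns and no rows.
#' @export
empty_annotations <- function() {
  data.frame(entity_type = character(0), begin = integer(0), end = integer(0),
             surface = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

.bind_annotations <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0L) return(empty_annotations())
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

# drop exact duplicates (same type/offsets), keeping the first source
.dedup_annotations <- function(ann) {
  if (nrow(ann) == 0L) return(ann)
  key <- paste(ann$entity_type, ann$begin, ann$end)
  ann <- ann[!duplicated(key), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}
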