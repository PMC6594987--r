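# Seeded generator of neuroscience-like annotated corpora. Sentences are
# built from slot templates over per-type lexicons, with distractor
# sentences, numeric ranges, unit-final value lists, parenthetical acronyms
# and overlapping region/neuron spans, so every statistical stage of the
# pipeline can be trained and evaluated without any external corpus.

.default_lexicons <- function() {
  adj <- c("ventral", "dorsal", "medial", "lateral", "rostral", "caudal",
           "anterior", "posterior")
  stem <- c("thalamic", "reticular", "geniculate", "posteromedial",
            "ventrobasal", "entopeduncular", "parafascicular", "peripeduncular",
            "suprageniculate", "retrosplenial", "paracentral", "submedius")
  head <- c("nucleus", "complex", "area")
  brain <- as.vector(outer(adj, outer(stem, head, paste)[, ], paste))
  ntype_mod <- c("pyramidal", "relay", "basket", "stellate", "granule",
                 "bipolar", "chandelier", "spiny", "fast-spiking", "bursting",
                 "thalamocortical", "corticothalamic")
  ntype <- as.vector(outer(ntype_mod, c("neurons", "cells"), paste))
  organisms <- c("rats", "mice", "rabbits", "ferrets", "cats", "macaques",
                 "rodents", "gerbils", "marmosets", "hamsters")
  fam <- c("T-type", "L-type", "N-type", "P-type", "R-type", "low-threshold",
           "high-threshold")
  ion <- c("Ca2+", "Na+", "K+")
  channels <- as.vector(outer(fam, paste(ion, "channels"), paste))
  currents <- as.vector(outer(fam, paste(ion, "currents"), paste))
  conduct <- as.vector(outer(fam, paste(ion, "conductance"), paste))
  units <- c("mV", "ms", "nA", "pA", "Hz", "mM", "microM", "ms", "mV")
  list(BrainRegion = brain, NeuronType = ntype, ModelOrganism = organisms,
       IonChannel = channels, IonCurrent = currents, IonConductance = conduct,
       Unit = units)
}

#' Configuration for the synthetic corpus generator
#'
#' @param seed Global seed; all sampling flows from one RNG seeded once.
#' @param n_documents Number of documents.
#' @param sentences_per_document Sentences per document.
#' @param type_weights Named non-negative weights over the entity types used
#'   when drawing each sentence's primary slot type; normalized to sum to 1.
#' @param distractor_frac Fraction of sentences with no gold entities.
#' @param heldout_frac Fraction of each lexicon reserved as held-out
#'   surface forms, so models are also exposed to forms unseen in the rest
#'   of the corpus.
#' @param heldout_prob Probability that a slot draws from the held-out part
#'   of its lexicon.
#' @param value_range Numeric range values are drawn from.
#' @param decimal_prob,thousands_prob Probabilities that a value is printed
#'   with one decimal place / with thousands grouping.
#' @param lexicons Per-type surface lists; defaults are built-in.
#' @return List of class `nm_genconfig`.
#' @export
generator_config <- function(seed = 42L, n_documents = 20L,
                             sentences_per_document = 10L,
                             type_weights = NULL, distractor_frac = 0.3,
                             heldout_frac = 0.25, heldout_prob = 0.15,
                             value_range = c(1, 200), decimal_prob = 0.3,
                             thousands_prob = 0.05, lexicons = NULL) {
  if (is.null(lexicons)) lexicons <- .default_lexicons()
  if (is.null(type_weights)) {
    type_weights <- c(BrainRegion = 0.22, NeuronType = 0.2,
                      ModelOrganism = 0.1, IonChannel = 0.1,
                      IonCurrent = 0.1, IonConductance = 0.08,
                      ExperimentalValue = 0.2)
  }
  stopifnot(all(names(type_weights) %in% ENTITY_TYPES),
            all(type_weights >= 0), sum(type_weights) > 0)
  for (ty in setdiff(names(lexicons), "Unit")) {
    if (length(lexicons[[ty]]) == 0L) {
      stop("empty lexicon for slot type ", ty)
    }
  }
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 type_weights = type_weights / sum(type_weights),
                 distractor_frac = distractor_frac,
                 heldout_frac = heldout_frac, heldout_prob = heldout_prob,
                 value_range = value_range, decimal_prob = decimal_prob,
                 thousands_prob = thousands_prob, lexicons = lexicons),
            class = "nm_genconfig")
}

.split_lexicon <- function(entries, heldout_frac) {
  n_held <- max(1L, floor(length(entries) * heldout_frac))
  held <- entries[seq_len(n_held)]            # deterministic: leading block
  list(train = setdiff(entries, held), heldout = held)
}

.draw_surface <- function(lex_split, heldout_prob) {
  pool <- if (runif(1) < heldout_prob && length(lex_split$heldout)) {
    lex_split$heldout
  } else lex_split$train
  pool[sample.int(length(pool), 1L)]
}

.format_value <- function(cfg) {
  v <- runif(1, cfg$value_range[1], cfg$value_range[2])
  if (runif(1) < cfg$decimal_prob) {
    sprintf("%.1f", v)
  } else if (runif(1) < cfg$thousands_prob) {
    formatC(round(v) * 1000, format = "d", big.mark = ",")
  } else {
    sprintf("%d", round(v))
  }
}

.DISTRACTORS <- c(
  "These results suggest that the protocol was robust and reproducible.",
  "The data were analysed offline with standard procedures.",
  "All experiments followed approved institutional guidelines.",
  "The authors declare that no competing interests exist.",
  "Further work will be required to clarify this mechanism.",
  "This observation is consistent with previous reports.",
  "The slices were maintained under continuous perfusion.",
  "Electrode placement was verified histologically after recording.")

# --- sentence builders: each returns list(text, gold, primary) with gold
#     offsets relative to the sentence ------------------------------------

.sb_fill <- function(template, pieces) {
  # template contains {i} placeholders referring to pieces[[i]] = list(text,
  # type or NULL); returns text + gold spans
  out <- ""
  gold <- empty_annotations()
  rest <- template
  repeat {
    m <- regexpr("\\{[0-9]+\\}", rest)
    if (m == -1L) { out <- paste0(out, rest); break }
    out <- paste0(out, substr(rest, 1L, m - 1L))
    idx <- as.integer(gsub("[{}]", "", regmatches(rest, m)))
    piece <- pieces[[idx]]
    b <- nchar(out)
    out <- paste0(out, piece$text)
    if (!is.null(piece$type)) {
      gold <- .bind_annotations(gold, span_annotation(
        piece$type, b, b + nchar(piece$text), piece$text, source = "gold"))
    }
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  list(text = out, gold = gold)
}

.sentence_builders <- function(cfg, lex) {
  draw <- function(ty) .draw_surface(lex[[ty]], cfg$heldout_prob)
  unit <- function() cfg$lexicons$Unit[sample.int(length(cfg$lexicons$Unit), 1L)]
  val_piece <- function(u) {
    # value with trailing unit: one ExperimentalValue over both, Unit on unit
    v <- .format_value(cfg)
    txt <- paste(v, u)
    list(text = txt, type = "ExperimentalValue", extra_unit = u)
  }
  list(
    BrainRegion = function() {
      ty <- draw("BrainRegion")
      tpl <- sample(c("Neurons were recorded in the {1} under anaesthesia.",
                      "Stimulation of the {1} evoked large responses.",
                      "The {1} receives dense afferent projections."), 1L)
      r <- .sb_fill(tpl, list(list(text = ty, type = "BrainRegion")))
      c(r, list(primary = "BrainRegion"))
    },
    NeuronType = function() {
      nt <- draw("NeuronType"); br <- draw("BrainRegion")
      tpl <- sample(c(
        "Whole-cell recordings were made from {1} in the {2}.",
        "Spontaneous firing of {1} was observed in the {2}.",
        "We recorded {1} located within the {2}."), 1L)
      r <- .sb_fill(tpl, list(list(text = nt, type = "NeuronType"),
                              list(text = br, type = "BrainRegion")))
      c(r, list(primary = "NeuronType"))
    },
    ModelOrganism = function() {
      mo <- draw("ModelOrganism"); br <- draw("BrainRegion")
      r <- .sb_fill("Slices were prepared from adult {1} and the {2} was identified.",
                    list(list(text = mo, type = "ModelOrganism"),
                         list(text = br, type = "BrainRegion")))
      c(r, list(primary = "ModelOrganism"))
    },
    IonChannel = function() {
      ic <- draw("IonChannel")
      r <- .sb_fill("Expression of {1} was strongest in dendrites.",
                    list(list(text = ic, type = "IonChannel")))
      c(r, list(primary = "IonChannel"))
    },
    IonCurrent = function() {
      ic <- draw("IonCurrent"); nt <- draw("NeuronType")
      r <- .sb_fill("The {1} was abolished in {2} after drug application.",
                    list(list(text = ic, type = "IonCurrent"),
                         list(text = nt, type = "NeuronType")))
      c(r, list(primary = "IonCurrent"))
    },
    IonConductance = function() {
      g <- draw("IonConductance")
      r <- .sb_fill("A slow {1} dominated the subthreshold response.",
                    list(list(text = g, type = "IonConductance")))
      c(r, list(primary = "IonConductance"))
    },
    ExperimentalValue = function() {
      u <- unit()
      kind <- sample.int(3L, 1L)
      if (kind == 1L) {          # single value with unit
        vp <- val_piece(u)
        r <- .sb_fill("Input resistance was {1} in these recordings.",
                      list(vp))
      } else if (kind == 2L) {   # range with minus signs
        v1 <- sprintf("%d", round(runif(1, 40, 120)))
        v2 <- sprintf("%d", round(runif(1, 10, 39)))
        txt <- paste0("−", v1, " to −", v2, " ", u)
        r <- .sb_fill("The membrane potential ranged from {1} during sleep.",
                      list(list(text = txt, type = "ExperimentalValue",
                                extra_unit = u)))
      } else {                   # unit-final list
        vs <- sprintf("%d", sort(round(runif(3, 1, 60))))
        txt <- paste0(vs[1], ", ", vs[2], " and ", vs[3], " ", u)
        r <- .sb_fill("Latencies of {1} were typical for this pathway.",
                      list(list(text = txt, type = "ExperimentalValue",
                                extra_unit = u)))
      }
      # add the Unit gold span at the end of the value span
      g <- r$gold
      vrow <- which(g$entity_type == "ExperimentalValue")[1L]
      ub <- g$end[vrow] - nchar(u)
      r$gold <- .bind_annotations(g, span_annotation("Unit", ub, g$end[vrow],
                                                     u, source = "gold"))
      c(r, list(primary = "ExperimentalValue"))
    })
}

# acronym + overlap document opener: introduces a long form with its
# acronym, then reuses the acronym, including the overlapping
# region-inside-neuron construction
.acronym_opener <- function(cfg, lex) {
  long <- .draw_surface(lex$BrainRegion, 0)  # always a train surface
  words <- strsplit(long, " ", fixed = TRUE)[[1]]
  acr <- toupper(paste(substr(words, 1, 1), collapse = ""))
  t1 <- .sb_fill("Recordings targeted the {1} ({2}) in every session.",
                 list(list(text = long, type = "BrainRegion"),
                      list(text = acr, type = "BrainRegion")))
  # overlap: "<ACR> neurons" is a NeuronType span containing a BrainRegion
  t2 <- .sb_fill("Burst firing of {1} was prominent at night.",
                 list(list(text = paste(acr, "neurons"), type = "NeuronType")))
  inner_b <- t2$gold$begin[1L]
  t2$gold <- .bind_annotations(
    t2$gold, span_annotation("BrainRegion", inner_b, inner_b + nchar(acr),
                             acr, source = "gold"))
  list(list(text = t1$text, gold = t1$gold, primary = "BrainRegion"),
       list(text = t2$text, gold = t2$gold, primary = "NeuronType"))
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the seed. Each document is a sequence of template
#' sentences: a weighted primary entity slot per sentence, a configurable
#' fraction of distractor sentences with no gold spans, numeric ranges with
#' Unicode minus signs, unit-final value lists, and (in the first sentence
#' pair of some documents) parenthetical acronym introductions and
#' overlapping region-inside-neuron spans.
#'
#' @param config From [generator_config()].
#' @return List of class `nm_corpus`: `documents` (list of `nm_document`),
#'   `annotations` (named list of gold span tables, raw text offsets), and
#'   `meta` (data.frame of document/sentence primary types).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "nm_genconfig"))
  .with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  lex <- lapply(cfg$lexicons[setdiff(names(cfg$lexicons), "Unit")],
                .split_lexicon, heldout_frac = cfg$heldout_frac)
  builders <- .sentence_builders(cfg, lex)
  wts <- cfg$type_weights
  docs <- list(); anns <- list()
  meta <- list()
  for (d in seq_len(cfg$n_documents)) {
    doc_id <- sprintf("doc%03d", d)
    sents <- list()
    if (runif(1) < 0.4) sents <- .acronym_opener(cfg, lex)
    while (length(sents) < cfg$sentences_per_document) {
      if (runif(1) < cfg$distractor_frac) {
        sents[[length(sents) + 1L]] <- list(
          text = sample(.DISTRACTORS, 1L), gold = empty_annotations(),
          primary = NA_character_)
      } else {
        ty <- sample(names(wts), 1L, prob = wts)
        sents[[length(sents) + 1L]] <- builders[[ty]]()
      }
    }
    text <- ""
    gold <- empty_annotations()
    bounds <- list()
    for (s in sents) {
      off <- nchar(text) + (nchar(text) > 0L)  # +1 for joining space
      text <- if (nzchar(text)) paste(text, s$text) else s$text
      if (nrow(s$gold)) {
        g <- s$gold
        g$begin <- g$begin + off; g$end <- g$end + off
        gold <- .bind_annotations(gold, g)
      }
      bounds[[length(bounds) + 1L]] <-
        data.frame(begin = off, end = off + nchar(s$text))
      meta[[length(meta) + 1L]] <- data.frame(
        doc_id = doc_id, sentence = length(bounds), primary = s$primary,
        stringsAsFactors = FALSE)
    }
    sent_df <- do.call(rbind, bounds)
    sent_df$text <- span_text(text, sent_df$begin, sent_df$end)
    docs[[doc_id]] <- document(doc_id, text, sent_df)
    anns[[doc_id]] <- gold
  }
  structure(list(documents = docs, annotations = anns,
                 meta = do.call(rbind, meta)),
            class = "nm_corpus")
}

#' @export
print.nm_corpus <- function(x, ...) {
  cat(sprintf("<nm_corpus: %d documents, %d gold spans>\n",
              length(x$documents), sum(vapply(x$annotations, nrow, integer(1)))))
  invisible(x)
}

#' Write a generated corpus as brat document pairs
#'
#' @param corpus From [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the document ids written.
#' @export
write_corpus_brat <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(corpus$documents)) {
    write_brat_files(corpus$documents[[id]], corpus$annotations[[id]],
                     file.path(dir, paste0(id, ".txt")),
                     file.path(dir, paste0(id, ".ann")))
  }
  invisible(names(corpus$documents))
}

#' Featurized sentences (with gold labels) from a corpus
#'
#' Tokenizes every sentence, builds the CRF feature rows, and fills the
#' gold BIO column for the requested entity type.
#'
#' @param corpus From [generate_corpus()].
#' @param entity_type Active entity type.
#' @param dictionary Dictionary entries for the Dict feature column
#'   (`NULL` for none).
#' @return List of featurized sentences.
#' @export
corpus_sentences <- function(corpus, entity_type, dictionary = NULL) {
  out <- list()
  for (id in names(corpus$documents)) {
    doc <- corpus$documents[[id]]
    gold <- corpus$annotations[[id]]
    for (i in seq_len(nrow(doc$sentences))) {
      b <- doc$sentences$begin[i]; e <- doc$sentences$end[i]
      toks <- tokenize(doc$sentences$text[i])
      toks$begin <- toks$begin + b; toks$end <- toks$end + b
      g <- gold[gold$begin >= b & gold$end <= e, , drop = FALSE]
      out[[length(out) + 1L]] <- build_features(toks, dictionary,
                                                entity_type, gold = g)
    }
  }
  out
}

#' Generate a seed set and an unlabelled pool for active learning
#'
#' Mirrors a two-stage annotation protocol: a small fully-annotated seed
#' set (default 15 documents) and a larger pool (default 160 documents)
#' whose gold annotations are hidden from selection and only used to
#' simulate annotation of selected sentences.
#'
#' @param config From [generator_config()]; its seed drives both corpora.
#' @param n_seed,n_pool Document counts for the two sets.
#' @param pool_distractor_frac Distractor fraction in the pool (pools of
#'   candidate sentences are mostly uninformative, which is what selection
#'   must overcome).
#' @return List with `seed` and `pool` corpora (documents disjoint by id).
#' @export
generate_al_pool <- function(config = generator_config(), n_seed = 15L,
                             n_pool = 160L, pool_distractor_frac = 0.7) {
  if (n_pool < 1L || n_seed < 1L) stop("n_seed and n_pool must be >= 1")
  seed_cfg <- config
  seed_cfg$n_documents <- as.integer(n_seed)
  pool_cfg <- config
  pool_cfg$n_documents <- as.integer(n_pool)
  pool_cfg$distractor_frac <- pool_distractor_frac
  pool_cfg$seed <- config$seed + 1L
  seed_corpus <- generate_corpus(seed_cfg)
  pool_corpus <- generate_corpus(pool_cfg)
  names(pool_corpus$documents) <- sub("^doc", "pool", names(pool_corpus$documents))
  names(pool_corpus$annotations) <- names(pool_corpus$documents)
  pool_corpus$meta$doc_id <- sub("^doc", "pool", pool_corpus$meta$doc_id)
  for (id in names(pool_corpus$documents)) {
    pool_corpus$documents[[id]]$doc_id <- id
  }
  list(seed = seed_corpus, pool = pool_corpus)
}
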