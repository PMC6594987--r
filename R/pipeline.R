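# Top-level pipeline: chain generation/rules/CRF training/active learning/
# evaluation into a reproducible run with a manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param types Entity types to process.
#' @param tagger `"rules"`, `"crf"` or `"neural"`.
#' @param al_n,al_k Active-learning hypothesis count and batch size.
#' @param split_ratios Train/test/validate shares.
#' @param seed Seed for splitting, training and generation.
#' @param generator Generator configuration ([generator_config()]) used when
#'   no input corpus directory is given.
#' @param corpus_dir Optional directory of brat `.txt`/`.ann` pairs used as
#'   the input corpus instead of generated data.
#' @return List of class `nm_pipeconfig`.
#' @export
pipeline_config <- function(out_dir, types = c("BrainRegion", "NeuronType"),
                            tagger = c("crf", "rules", "neural"),
                            al_n = 3L, al_k = 500L,
                            split_ratios = c(0.70, 0.15, 0.15), seed = 1L,
                            generator = generator_config(seed = seed),
                            corpus_dir = NULL) {
  tagger <- match.arg(tagger)
  if (al_n < 1L || al_k < 1L) stop("al_n and al_k must be >= 1")
  stopifnot(all(types %in% ENTITY_TYPES))
  structure(list(out_dir = out_dir, types = types, tagger = tagger,
                 al_n = as.integer(al_n), al_k = as.integer(al_k),
                 split_ratios = split_ratios, seed = as.integer(seed),
                 generator = generator, corpus_dir = corpus_dir),
            class = "nm_pipeconfig")
}

.load_brat_dir <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(txts) == 0L) stop("no .txt documents in ", dir)
  docs <- list(); anns <- list()
  for (tp in txts) {
    ap <- sub("\\.txt$", ".ann", tp)
    r <- read_brat_files(tp, ap)
    docs[[r$document$doc_id]] <- r$document
    anns[[r$document$doc_id]] <- r$annotations
  }
  structure(list(documents = docs, annotations = anns, meta = NULL),
            class = "nm_corpus")
}

#' Run the end-to-end pipeline
#'
#' Stages: obtain the corpus (generate or load brat), run the rule
#' annotator, split sentences 70/15/15, train the chosen tagger per entity
#' type on the training partition, evaluate on the test partition under
#' both strict and relaxed matching, and write all artifacts plus a
#' manifest of configuration, seed and content hashes. Any stage failure
#' aborts with the stage name.
#'
#' @param config From [pipeline_config()].
#' @return List with `reports` (per type), `manifest`, and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nm_pipeconfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  corpus <- stage("corpus", {
    if (is.null(config$corpus_dir)) generate_corpus(config$generator)
    else .load_brat_dir(config$corpus_dir)
  })
  stage("rules", {
    rules_dir <- file.path(out, "rules")
    dir.create(rules_dir, showWarnings = FALSE)
    for (id in names(corpus$documents)) {
      ann <- annotate_rules(corpus$documents[[id]])
      writeLines(write_brat(ann), file.path(rules_dir, paste0(id, ".ann")))
    }
  })
  reports <- list()
  if (config$tagger %in% c("crf", "neural")) {
    for (ty in config$types) {
      reports[[ty]] <- stage(paste0("train-", ty), {
        sents <- corpus_sentences(corpus, ty)
        has_gold <- vapply(sents, function(s) any(s$GoldLabel != "O"), logical(1))
        if (!any(has_gold)) stop("no gold spans for ", ty)
        sp <- split_corpus(length(sents), config$split_ratios, config$seed)
        if (config$tagger == "crf") {
          model <- crf_train(sents[sp$train], ty, seed = config$seed)
          crf_save(model, file.path(out, paste0("crf_", ty, ".rds")))
          pred <- lapply(sents[sp$test], function(s) crf_predict(model, s))
        } else {
          cfg <- nn_config(seed = config$seed, word_embed_dim = 32L,
                           char_embed_dim = 12L, char_word_dim = 24L,
                           word_hidden = 32L, epochs = 12L)
          model <- nn_train(sents[sp$train], ty, cfg)
          nn_save(model, file.path(out, paste0("nn_", ty, ".rds")))
          pred <- nn_tag(model, sents[sp$test])
        }
        .eval_bio(sents[sp$test], pred, ty)
      })
    }
  } else {
    for (ty in intersect(config$types, names(.DICT_FILES))) {
      reports[[ty]] <- stage(paste0("rules-eval-", ty), {
        gold_all <- list(); pred_all <- list()
        for (id in names(corpus$documents)) {
          gold <- corpus$annotations[[id]]
          pred <- annotate_rules(corpus$documents[[id]], types = ty)
          gold_all[[id]] <- gold[gold$entity_type == ty, , drop = FALSE]
          pred_all[[id]] <- pred[pred$entity_type == ty, , drop = FALSE]
        }
        ag <- agreement_f1(gold_all, pred_all)
        ag[ag$entity_type == ty, , drop = FALSE]
      })
    }
  }
  manifest <- list(
    seed = config$seed, tagger = config$tagger, types = config$types,
    n_documents = length(corpus$documents),
    corpus_hash = .digest_corpus(corpus),
    timestamp = NA_character_)  # deliberately constant for reproducibility
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(reports = reports, manifest = manifest, out_dir = out)
}

# BIO-level evaluation helper: spans decoded from predicted labels vs gold
.eval_bio <- function(sents, preds, entity_type) {
  gold_all <- empty_annotations(); pred_all <- empty_annotations()
  shift <- 0L
  for (i in seq_along(sents)) {
    s <- sents[[i]]
    toks <- data.frame(surface = s$Word, begin = s$Begin + shift,
                       end = s$End + shift, stringsAsFactors = FALSE)
    gold_all <- .bind_annotations(
      gold_all, bio_to_spans(toks, s$GoldLabel, entity_type))
    pred_all <- .bind_annotations(
      pred_all, bio_to_spans(toks, preds[[i]], entity_type, source = "crf"))
    shift <- shift + max(0L, s$End) + 10L
  }
  strict <- prf(pred_all, gold_all, "strict")
  relaxed <- prf(pred_all, gold_all, "relaxed")
  data.frame(entity_type = entity_type,
             mode = c("strict", "relaxed"),
             precision = c(strict$precision, relaxed$precision),
             recall = c(strict$recall, relaxed$recall),
             f1 = c(strict$f1, relaxed$f1), stringsAsFactors = FALSE)
}

# content hash without external digest packages: DJB2 over serialized text
.digest_corpus <- function(corpus) {
  txt <- paste(vapply(corpus$documents, function(d) d$text, character(1)),
               collapse = "\x01")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2147483647
  sprintf("%d", h)
}
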