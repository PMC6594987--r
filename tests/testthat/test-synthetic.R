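test_that("generation is deterministic and internally consistent", {
  c1 <- make_corpus(seed = 5, docs = 6, sents = 6)
  c2 <- make_corpus(seed = 5, docs = 6, sents = 6)
  expect_identical(lapply(c1$documents, `[[`, "text"),
                   lapply(c2$documents, `[[`, "text"))
  expect_identical(c1$annotations, c2$annotations)
  c3 <- make_corpus(seed = 6, docs = 6, sents = 6)
  expect_false(identical(lapply(c1$documents, `[[`, "text"),
                         lapply(c3$documents, `[[`, "text")))
  # every gold surface equals the text at its offsets
  for (id in names(c1$documents)) {
    g <- c1$annotations[[id]]
    if (nrow(g)) {
      expect_identical(span_text(c1$documents[[id]]$text, g$begin, g$end),
                       g$surface)
    }
  }
})

test_that("realized primary-type frequencies follow the configured weights", {
  cfg <- generator_config(seed = 101, n_documents = 60,
                          sentences_per_document = 12, distractor_frac = 0)
  corpus <- generate_corpus(cfg)
  draws <- corpus$meta$primary[!is.na(corpus$meta$primary)]
  n <- length(draws)
  expect_gte(n, 500L)
  w <- cfg$type_weights
  for (ty in names(w)) {
    p <- w[[ty]]
    sigma <- sqrt(n * p * (1 - p))
    expect_lte(abs(sum(draws == ty) - n * p), 3 * sigma + 1)
  }
})

test_that("gold spans are token-aligned and distractors carry no gold", {
  corpus <- make_corpus(seed = 9, docs = 8, sents = 8)
  for (id in names(corpus$documents)) {
    doc <- corpus$documents[[id]]
    toks <- tokenize(doc$text)
    g <- corpus$annotations[[id]]
    if (nrow(g)) {
      expect_true(all(g$begin %in% toks$begin))
      expect_true(all(g$end %in% toks$end))
    }
  }
  meta <- corpus$meta
  for (r in which(is.na(meta$primary))) {
    doc <- corpus$documents[[meta$doc_id[r]]]
    b <- doc$sentences$begin[meta$sentence[r]]
    e <- doc$sentences$end[meta$sentence[r]]
    g <- corpus$annotations[[meta$doc_id[r]]]
    expect_equal(sum(g$begin >= b & g$end <= e), 0L)
  }
})

test_that("generated corpora include overlap, range and acronym constructs", {
  cfg <- generator_config(seed = 12, n_documents = 25,
                          sentences_per_document = 8)
  corpus <- generate_corpus(cfg)
  all_ann <- do.call(rbind, corpus$annotations)
  # a region span strictly inside a neuron span (same offsets overlap)
  found_overlap <- FALSE
  for (id in names(corpus$annotations)) {
    g <- corpus$annotations[[id]]
    br <- g[g$entity_type == "BrainRegion", ]
    nt <- g[g$entity_type == "NeuronType", ]
    for (i in seq_len(nrow(br))) {
      if (any(nt$begin <= br$begin[i] & nt$end >= br$end[i])) found_overlap <- TRUE
    }
  }
  expect_true(found_overlap)
  expect_true(any(grepl("−", all_ann$surface)))          # ranges with minus
  expect_true(any(grepl(" and ", all_ann$surface)))      # unit-final lists
  expect_true(any(vapply(corpus$documents, function(d) {
    nrow(find_abbreviations(d$text)) > 0
  }, logical(1))))                                        # acronym pairs
})

test_that("generated brat files are re-read losslessly", {
  corpus <- make_corpus(seed = 31, docs = 3, sents = 6)
  dir <- withr::local_tempdir()
  write_corpus_brat(corpus, dir)
  for (id in names(corpus$documents)) {
    r <- read_brat_files(file.path(dir, paste0(id, ".txt")),
                         file.path(dir, paste0(id, ".ann")))
    expect_identical(r$document$text, corpus$documents[[id]]$text)
    expect_equal(nrow(r$annotations), nrow(corpus$annotations[[id]]))
  }
})

test_that("the active-learning pool mirrors the seed/pool protocol", {
  cfg <- generator_config(seed = 77, n_documents = 5,
                          sentences_per_document = 5)
  al <- generate_al_pool(cfg, n_seed = 4, n_pool = 9)
  expect_length(al$seed$documents, 4L)
  expect_length(al$pool$documents, 9L)
  expect_length(intersect(names(al$seed$documents), names(al$pool$documents)), 0L)
  # defaults mirror the two-round protocol sizes
  expect_identical(formals(generate_al_pool)$n_seed, 15L)
  expect_identical(formals(generate_al_pool)$n_pool, 160L)
  expect_error(generate_al_pool(cfg, n_seed = 0), ">= 1")
  expect_error(generator_config(lexicons = list(BrainRegion = character(0))),
               "empty lexicon")
})
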