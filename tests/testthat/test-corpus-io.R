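test_that("tokenizer detaches punctuation, splits hyphen compounds, keeps offsets exact", {
  toks <- tokenize(TABLE_SENT, mode = "detokenized")
  expect_equal(toks$surface[1:4], c("Abstract", ":", "Whole", "-cell"))
  expect_equal(toks$begin[1:4], c(0L, 9L, 11L, 17L))
  expect_equal(toks$end[1:4], c(8L, 10L, 16L, 22L))
  expect_equal(toks$surface[17:19], c("(", "VPM", ")"))
  expect_equal(toks$begin[17:19], c(100L, 102L, 106L))
  expect_equal(toks$end[17:19], c(101L, 105L, 107L))
  expect_true(all(toks$end - toks$begin == nchar(toks$surface)))
  # decimals and digit-adjacent hyphens stay intact
  t2 <- tokenize("bicuculline (12.5 microM) at 10-20mv")
  expect_true("12.5" %in% t2$surface)
  expect_true("10-20mv" %in% t2$surface)
  expect_equal(nrow(tokenize("")), 0L)
})

test_that("tokenization is idempotent under space-joining", {
  set.seed(41)
  words <- c("the", "neuron", "fired", "at", "12.5", "mV", "(", ")", ":",
             "Whole", "-cell", "rats", ",", "T", "-type")
  for (k in 1:20) {
    s <- paste(sample(words, sample(3:10, 1), replace = TRUE), collapse = " ")
    t1 <- tokenize(s, mode = "detokenized")
    t2 <- tokenize(detokenize(t1), mode = "detokenized")
    expect_identical(t1, t2)
  }
})

test_that("raw offsets index the original text", {
  s <- "A  b   (c)"  # irregular spacing
  toks <- tokenize(s, mode = "raw")
  expect_equal(span_text(s, toks$begin, toks$end), toks$surface)
})

test_that("sentence splitter respects abbreviation guards", {
  s <- "Cells fired fast. The rate was 5 Hz (e.g. in vivo). Firing stopped."
  sp <- split_sentences(s)
  expect_equal(nrow(sp), 3L)
  expect_equal(span_text(s, sp$begin, sp$end), sp$text)
  s2 <- "Values rose (cf. Fig. 2) over time. No change followed."
  expect_equal(nrow(split_sentences(s2)), 2L)
  expect_equal(nrow(split_sentences("")), 0L)
})

test_that("spans_to_bio encodes the printed feature-table example", {
  toks <- tokenize(TABLE_SENT, mode = "detokenized")
  ann <- span_annotation("BrainRegion", c(67L, 102L), c(99L, 105L),
                         c("ventral posterior medial nucleus", "VPM"))
  bio <- spans_to_bio(toks, ann, "BrainRegion")
  expect_equal(bio[13:16], c("B-BrainRegion", rep("I-BrainRegion", 3)))
  expect_equal(bio[18], "B-BrainRegion")
  expect_true(all(bio[-c(13:16, 18)] == "O"))
  expect_true(all(spans_to_bio(toks, empty_annotations(), "BrainRegion") == "O"))
  # other types are ignored
  ann2 <- span_annotation("NeuronType", 0L, 8L, "Abstract")
  expect_true(all(spans_to_bio(toks, ann2, "BrainRegion") == "O"))
})

test_that("bio_to_spans inverts spans_to_bio on token-aligned span sets", {
  set.seed(91)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    toks <- data.frame(surface = replicate(n, paste(sample(letters, 3), collapse = "")),
                       stringsAsFactors = FALSE)
    toks$begin <- cumsum(c(0L, head(nchar(toks$surface), -1L) + 1L))
    toks$end <- toks$begin + nchar(toks$surface)
    # random non-overlapping token-aligned spans
    starts <- sort(sample(n, sample(0:2, 1)))
    spans <- empty_annotations()
    used <- 0L
    for (s in starts) {
      if (s <= used) next
      e <- min(n, s + sample(0:2, 1))
      spans <- rbind(spans, span_annotation(
        "NeuronType", toks$begin[s], toks$end[e],
        paste(toks$surface[s:e], collapse = " ")))
      used <- e
    }
    bio <- spans_to_bio(toks, spans, "NeuronType")
    back <- bio_to_spans(toks, bio, "NeuronType")
    expect_equal(back[c("entity_type", "begin", "end", "surface")],
                 spans[c("entity_type", "begin", "end", "surface")])
  }
})

test_that("bio_to_spans repairs dangling I- labels and checks alignment", {
  toks <- tokenize("alpha beta gamma")
  expect_warning(sp <- bio_to_spans(toks, c("I-Unit", "I-Unit", "O"), "Unit"),
                 "dangling")
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$begin, 0L)
  expect_equal(sp$end, toks$end[2])
  expect_error(bio_to_spans(toks, c("O", "O"), "Unit"), "mismatch")
  expect_equal(nrow(bio_to_spans(toks, rep("O", 3), "Unit")), 0L)
  # boundary-crossing annotation snaps outward with a warning
  ann <- span_annotation("Unit", 1L, 4L, "lph")
  expect_warning(bio <- spans_to_bio(toks, ann, "Unit"), "snapped")
  expect_equal(bio[1], "B-Unit")
  expect_error(spans_to_bio(toks, ann, "Unit", boundary_policy = "reject"),
               "crosses")
})

test_that("brat reader keeps overlapping types and validates surfaces", {
  txt <- "Recordings in VB Neurons were stable."
  ann <- c("T1\tBrainRegion 14 16\tVB",
           "T2\tNeuronType 14 24\tVB Neurons")
  r <- read_brat(txt, ann)
  expect_equal(nrow(r$annotations), 2L)
  expect_equal(sort(r$annotations$entity_type), c("BrainRegion", "NeuronType"))
  # overlap is preserved
  expect_true(r$annotations$begin[1] == r$annotations$begin[2])
  expect_equal(nrow(read_brat(txt, character(0))$annotations), 0L)
  expect_error(read_brat(txt, "T1\tBrainRegion 14 16\tXX"), "mismatch")
  expect_warning(r2 <- read_brat(txt, c(ann, "T3\tGene 0 10\tRecordings")),
                 "unknown entity type")
  expect_equal(nrow(r2$annotations), 2L)
  expect_warning(read_brat(txt, c(ann, "R1\tPartOf Arg1:T1 Arg2:T2")),
                 "non-T")
})

test_that("brat write/read round-trips generated corpora", {
  corpus <- make_corpus(seed = 19, docs = 4, sents = 6)
  dir <- withr::local_tempdir()
  write_corpus_brat(corpus, dir)
  for (id in names(corpus$documents)) {
    r <- read_brat_files(file.path(dir, paste0(id, ".txt")),
                         file.path(dir, paste0(id, ".ann")))
    expect_identical(r$document$text, corpus$documents[[id]]$text)
    a <- corpus$annotations[[id]]
    a <- a[order(a$begin, a$end, a$entity_type), ]
    b <- r$annotations[order(r$annotations$begin, r$annotations$end,
                             r$annotations$entity_type), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b[c("entity_type", "begin", "end", "surface")],
                 a[c("entity_type", "begin", "end", "surface")])
  }
})

test_that("TSV interchange round-trips byte-identically", {
  toks <- tokenize(TABLE_SENT, mode = "detokenized")
  feat <- build_features(toks, load_dictionary("BrainRegion"), "BrainRegion")
  corpus <- make_corpus(seed = 23, docs = 2, sents = 4)
  feats <- corpus_sentences(corpus, "NeuronType")
  sents <- c(list(feat), feats)
  lines <- write_tsv(sents)
  back <- read_tsv(lines)
  expect_identical(write_tsv(back), lines)
  expect_equal(length(back), length(sents))
  expect_identical(back[[1]]$Word, feat$Word)
  expect_identical(back[[1]]$Begin, feat$Begin)
  expect_identical(write_tsv(list()), character(0))
  expect_error(read_tsv(c("1\t2\tonly-three")), "fields")
  # file round trip
  p <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(sents, p)
  expect_identical(write_tsv(read_tsv(p)), lines)
})
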