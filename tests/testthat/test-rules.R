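test_that("dictionary matching is leftmost-longest with acronym case rules", {
  d <- load_dictionary("BrainRegion")
  t1 <- tokenize("curve partially around the rostral pole of the ventral posteromedial nucleus (VPM)")
  m1 <- dict_match(t1, d, "BrainRegion")
  expect_setequal(m1$surface, c("ventral posteromedial nucleus", "VPM"))
  t2 <- tokenize("and the other population projected mainly to orbital or cingulate areas.")
  expect_equal(nrow(dict_match(t2, d, "BrainRegion")), 0L)
  t3 <- tokenize("from the rat ventrobasal complex (VB) and posterior nucleus (POm).")
  m3 <- dict_match(t3, d, "BrainRegion")
  expect_setequal(m3$surface, c("ventrobasal complex", "nucleus"))
  expect_equal(nrow(dict_match(t1, character(0), "BrainRegion")), 0L)
  # short entries are case-sensitive: "vpm" must not match the acronym
  t4 <- tokenize("the vpm region")
  expect_false("vpm" %in% dict_match(t4, d, "BrainRegion")$surface)
})

test_that("dictionary matches agree with a brute-force oracle and never overlap", {
  d <- c("ventral posteromedial nucleus", "nucleus", "VPM", "ventrobasal complex")
  set.seed(17)
  vocab <- c("the", "ventral", "posteromedial", "nucleus", "VPM", "of",
             "ventrobasal", "complex", "and", "cells")
  for (k in 1:30) {
    s <- paste(sample(vocab, sample(4:12, 1), replace = TRUE), collapse = " ")
    toks <- tokenize(s)
    got <- dict_match(toks, d, "BrainRegion")
    want <- bf_dict_match(toks, d)
    expect_equal(nrow(got), length(want))
    if (nrow(got)) {
      expect_equal(got$begin, vapply(want, `[`, numeric(1), 1))
      expect_equal(got$end, vapply(want, `[`, numeric(1), 2))
      expect_true(all(got$begin[-1] >= head(got$end, -1)))
    }
  }
})

test_that("noun-phrase regexes assign the whole phrase to the matched type", {
  s1 <- "T-type Ca2+ channels were blocked"
  m1 <- regex_np_match(noun_phrases(tokenize(s1)), "IonChannel", text = s1)
  expect_equal(m1$surface, "T-type Ca2+ channels")
  s2 <- "a T-type Ca2+ conductance was present"
  m2 <- regex_np_match(noun_phrases(tokenize(s2)), "IonConductance", text = s2)
  expect_equal(nrow(m2), 1L)
  expect_match(m2$surface, "T-type Ca2\\+ conductance")
  s3 <- "the membrane potential was stable"
  expect_equal(nrow(regex_np_match(noun_phrases(tokenize(s3)), "all")), 0L)
  s4 <- "SCN neurons fired at night"
  m4 <- regex_np_match(noun_phrases(tokenize(s4)), "NeuronType", text = s4)
  expect_equal(m4$surface, "SCN neurons")
})

test_that("unit gazetteer expansion has the documented sizes and forms", {
  gaz <- unit_gazetteer()
  expect_length(gaz$bases$long, 24L)
  expect_length(gaz$prefixes$long, 19L)
  forms <- expand_unit_gazetteer(gaz)
  long <- forms$form[forms$kind == "long"]
  expect_length(long, 24L * (19L + 1L))
  expect_true(all(c("milligram", "kilometre", "millivolt", "microgram") %in% long))
  expect_true("volt" %in% long)   # bare base, no prefix
  short <- forms$form[forms$kind == "short"]
  expect_true(all(c("mg", "km", "mm", "mV") %in% short))
  expect_true("microM" %in% forms$form)  # mixed long prefix + short base
  expect_true(all(forms$case_sensitive[forms$kind != "long"]))
})

test_that("unit matching is case-sensitive for short forms and finds fused units", {
  u1 <- match_units("held at 10-20mv overnight")
  expect_true("mv" %in% u1$surface)
  u2 <- match_units("a span of 3 km and 2 mg doses")
  expect_setequal(u2$surface, c("km", "mg"))
  # plural long forms
  u3 <- match_units("45 millimetres of tissue")
  expect_equal(u3$surface, "millimetres")
  # "MV" (mega-volt) is not "mV"
  u4 <- match_units("recorded in mV units")
  expect_equal(u4$surface[1], "mV")
})

test_that("value detection matches the documented grammar", {
  v1 <- detect_values("numbers such as 1100, 23,400,500 or 345,600,700,800")
  expect_equal(v1$surface, c("1100", "23,400,500", "345,600,700,800"))
  expect_equal(v1$value, c(1100, 23400500, 345600700800))
  expect_equal(nrow(detect_values("1.1.1.1 is an address")), 0L)
  expect_equal(nrow(detect_values("bad groupings 1,23 and 34,567,1 here")), 0L)
  v2 <- detect_values("a range (e.g., −100 to − 40 mV)")
  expect_equal(v2$value, c(-100, -40))
  expect_equal(v2$surface, c("−100", "− 40"))
  # list context: the hyphen in 10-20 does not negate the 20
  v3 <- detect_values("E.g. 10-20mv")
  expect_equal(v3$value, c(10, 20))
  # every surface parses as a number under the 1,234,567.89 convention
  set.seed(5)
  txt <- paste(c("12.5", "1,234,567.89", "7", "3,000", "x1.1.1", "0.25"),
               collapse = " and ")
  v4 <- detect_values(txt)
  expect_true(all(!is.na(v4$value)))
})

test_that("value-unit linking covers adjacency, ranges and unit-final lists", {
  s1 <- "The effect of bicuculline (12.5 microM) was heterogeneous."
  toks <- tokenize(s1); nps <- noun_phrases(toks)
  l1 <- link_value_unit(detect_values(s1), match_units(s1), nps, s1)
  expect_equal(nrow(l1$annotations), 1L)
  expect_equal(l1$annotations$surface, "12.5 microM")
  expect_equal(l1$links$value_num, 12.5)
  expect_equal(l1$links$unit_surface, "microM")

  s2 <- "measured 10-20mv during the night"
  l2 <- link_value_unit(detect_values(s2), match_units(s2),
                        noun_phrases(tokenize(s2)), s2)
  expect_equal(l2$links$unit_surface, c("mv", "mv"))
  expect_equal(l2$links$value_num, c(10, 20))

  s3 <- "lengths of 15, 30 and 45 millimetres were used"
  l3 <- link_value_unit(detect_values(s3), match_units(s3),
                        noun_phrases(tokenize(s3)), s3)
  expect_equal(l3$links$value_num, c(15, 30, 45))
  expect_true(all(l3$links$unit_surface == "millimetres"))
  # no values silently dropped
  expect_gte(nrow(l3$annotations), nrow(detect_values(s3)))

  # sample sizes are excluded
  s4 <- "responses (n = 12) were recorded at 5 mV"
  l4 <- link_value_unit(detect_values(s4), match_units(s4),
                        noun_phrases(tokenize(s4)), s4)
  expect_false(12 %in% l4$links$value_num)
  expect_true(5 %in% l4$links$value_num)
})

test_that("parenthetical abbreviations are found with character-overlap validation", {
  a1 <- find_abbreviations("slices of the suprachiasmatic nucleus (SCN) of adult rats")
  expect_equal(a1$long_form, "suprachiasmatic nucleus")
  expect_equal(a1$short_form, "SCN")
  expect_equal(nrow(find_abbreviations("no parentheses here at all")), 0L)
  a2 <- find_abbreviations("from the ventrobasal complex (VB) and posterior nucleus (POm).")
  expect_equal(a2$long_form, c("ventrobasal complex", "posterior nucleus"))
  expect_equal(a2$short_form, c("VB", "POm"))
  # a mismatching short form is rejected
  expect_equal(nrow(find_abbreviations("the big value (XQZ) appeared")), 0L)
})

test_that("acronym propagation assigns the long form's type to every mention", {
  txt <- paste("Recordings in the suprachiasmatic nucleus (SCN) were made.",
               "Activity of SCN cells was high. The SCN controls rhythm.")
  ann <- annotate_rules(txt, types = "BrainRegion")
  scn <- ann[ann$surface == "SCN", ]
  expect_equal(nrow(scn), 3L)
  expect_true(all(scn$entity_type == "BrainRegion"))
  expect_true(all(scn$source == "acronym"))
  # unannotated long forms propagate nothing
  abbr <- find_abbreviations("the quick brown fox (QBF) jumped; QBF again")
  out <- propagate_acronyms("the quick brown fox (QBF) jumped; QBF again",
                            empty_annotations(), abbr)
  expect_equal(nrow(out), 0L)
  # two acronyms of different types each receive only their own type
  txt2 <- paste("Cells of the ventrobasal complex (VB) and normal rats (NR)",
                "were compared; VB responses differed in NR preparations.")
  ann2 <- span_annotation(c("BrainRegion", "ModelOrganism"),
                          c(13L, 42L), c(32L, 53L),
                          c("ventrobasal complex", "normal rats"))
  abbr2 <- find_abbreviations(txt2)
  out2 <- propagate_acronyms(txt2, ann2, abbr2)
  vb <- out2[out2$surface == "VB", ]
  nr <- out2[out2$surface == "NR", ]
  expect_true(all(vb$entity_type == "BrainRegion"))
  expect_true(all(nr$entity_type == "ModelOrganism"))
})

test_that("the conductance dictionary is the stated rewrite of the current dictionary", {
  cur <- load_dictionary("IonCurrent")
  expect_identical(load_dictionary("IonConductance"),
                   derive_conductance_dictionary(cur))
  expect_true("gH" %in% derive_conductance_dictionary("IH"))
  expect_equal(derive_conductance_dictionary("T-type calcium current"),
               "T-type calcium conductance")
})
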