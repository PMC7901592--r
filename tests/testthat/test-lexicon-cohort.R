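test_that("with no synonym-labeled candidates the lexicon equals the seeds", {
  seeds <- list(fever = "fever", cough = c("cough", "tussis"))
  ann <- make_annotations(A1 = c("hypernym", "other"), A2 = c("hypernym", "other"),
                          query = "fever")
  lex <- build_expanded_lexicon(seeds, ann)
  expect_identical(sort(lex$term), sort(c("fever", "cough", "tussis")))
  expect_true(all(lex$tag == "seed"))
})

test_that("synonym-labeled candidates join their concept with provenance", {
  seeds <- list(fever = "fever")
  ann <- dplyr::bind_rows(lapply(c("s1", "s2", "s3"), function(s) {
    tibble::tibble(
      query = "fever",
      returned = c("pyrexia", "fevers", "febrile", "chills"),
      source = s, annotator = "A1",
      label = c("synonym", "synonym", "synonym", "symptom_sign")
    )
  }))
  ann <- dplyr::bind_rows(
    ann,
    dplyr::mutate(ann, annotator = "A2"),
    dplyr::mutate(ann, annotator = "A3")
  )
  lex <- build_expanded_lexicon(seeds, ann)
  learned <- lex[lex$tag == "learned", ]
  expect_setequal(learned$term, c("pyrexia", "fevers", "febrile"))
  # same term from 3 sources appears once with all three recorded
  expect_identical(learned$sources[learned$term == "pyrexia"], "s1,s2,s3")
  expect_false("chills" %in% lex$term)
  # seeds always retained
  expect_true("fever" %in% lex$term[lex$tag == "seed"])
})

test_that("the consensus and any-annotator expansion rules differ as designed", {
  seeds <- list(fever = "fever")
  # one annotator says synonym, two disagree
  ann <- make_annotations(A1 = "synonym", A2 = "hypernym", A3 = "hypernym")
  expect_false("cand_001" %in% build_expanded_lexicon(seeds, ann)$term)
  expect_true("cand 001" %in%
                build_expanded_lexicon(seeds, ann, rule = "any")$term)
  expect_error(
    build_expanded_lexicon(seeds, make_annotations(A1 = "synonym",
                                                   A2 = "synonym",
                                                   query = "wheeze")),
    "outside the seed concepts"
  )
})

test_that("lexicons round-trip through their tab-separated format", {
  seeds <- list(fever = "fever")
  ann <- make_annotations(A1 = "synonym", A2 = "synonym")
  lex <- build_expanded_lexicon(seeds, ann)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_identical(as.data.frame(back), as.data.frame(lex))
})

test_that("feature matching is word-boundary-safe and delimiter tolerant", {
  lex <- toy_lexicon()
  notes <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4", "p5"),
    cohort = "A",
    note_text = c(
      "patient reports Fever and chills today",
      "persistent feverish coughing noted",     # no word-boundary match
      "hypoxemia resolved overnight",
      "no complaints recorded",
      ""                                         # empty note matches nothing
    )
  )
  m <- match_features(notes, lex)
  wide <- tidyr::pivot_wider(m, names_from = "concept", values_from = "matched")
  expect_true(wide$fever[wide$patient_id == "p1"])
  expect_true(wide$chills[wide$patient_id == "p1"])
  expect_false(wide$fever[wide$patient_id == "p2"])   # "feverish" is not "fever"
  expect_true(wide$hypoxia[wide$patient_id == "p3"])  # learned-term spelling
  expect_false(any(unlist(wide[wide$patient_id == "p5", lex$concept[1]])))
})

test_that("multi-word terms match across single spaces and delimiter variants", {
  lex <- build_expanded_lexicon(list("dry cough" = "dry cough"))
  notes <- tibble::tibble(
    patient_id = sprintf("p%d", 1:5),
    cohort = "A",
    note_text = c(
      "presents with dry cough since monday",
      "presents with dry-cough since monday",
      "presents with dry_cough since monday",
      "presents with dry  persistent cough",   # tokens separated: no match
      "dryish coughing"
    )
  )
  m <- match_features(notes, lex)
  expect_identical(m$matched, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("any note of a patient can establish a concept", {
  lex <- toy_lexicon()
  notes <- tibble::tibble(
    patient_id = c("p1", "p1", "p1"),
    cohort = "A",
    note_text = c("routine visit", "stable overnight", "pyrexia documented")
  )
  m <- match_features(notes, lex)
  expect_true(m$matched[m$concept == "fever"])
  dup <- dplyr::bind_rows(notes, notes[1, ])
  expect_error(match_features(dup, lex), "duplicate")
})

test_that("feature proportions are exact fractions with cohort denominators", {
  lex <- toy_lexicon()
  notes <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:10),
    cohort = "A",
    note_text = c(rep("fever noted", 4), rep("nothing to report", 6))
  )
  props <- feature_proportions(match_features(notes, lex))
  fever <- props[props$concept == "fever", ]
  expect_identical(fever$numerator, 4L)
  expect_identical(fever$denominator, 10L)
  expect_equal(fever$proportion, 0.4)
  expect_true(all(props$numerator <= props$denominator))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_proportions(props, path)
  written <- utils::read.delim(path)
  expect_equal(written$proportion[written$concept == "fever"], 0.40)
})

test_that("adding lexicon terms or notes never decreases a proportion", {
  base_lex <- build_expanded_lexicon(list(fever = "fever"))
  grown_lex <- build_expanded_lexicon(
    list(fever = "fever"),
    make_annotations(A1 = "synonym", A2 = "synonym")  # adds "cand 001"
  )
  notes <- tibble::tibble(
    patient_id = sprintf("p%d", 1:4),
    cohort = "A",
    note_text = c("fever", "cand 001 seen", "well", "well")
  )
  p_base <- feature_proportions(match_features(notes, base_lex))
  p_grown <- feature_proportions(match_features(notes, grown_lex))
  expect_true(all(p_grown$proportion >= p_base$proportion))

  more_notes <- dplyr::bind_rows(
    notes, tibble::tibble(patient_id = "p3", cohort = "A", note_text = "fever too")
  )
  p_more <- feature_proportions(match_features(more_notes, base_lex))
  expect_true(all(p_more$proportion >= p_base$proportion))
})

test_that("severity groups apply their conjunction and disjunction rules", {
  concepts <- unique(unlist(lapply(severity_group_map(),
                                   function(g) c(g$anchor, g$features))))
  make_match <- function(positive) {
    tidyr::expand_grid(patient_id = "p1", cohort = "A", concept = concepts) |>
      dplyr::mutate(matched = concept %in% positive)
  }
  roll <- function(positive) severity_rollup(make_match(positive))

  only_cough <- roll("cough")
  expect_true(only_cough$`mild illness`)
  expect_false(only_cough$`moderate pneumonia`)

  mod <- roll(c("cough", "shortness of breath"))
  expect_true(mod$`moderate pneumonia`)

  sev <- roll(c("fever", "hypoxia"))
  expect_true(sev$`severe pneumonia/ARDS`)
  expect_false(roll("fever")$`severe pneumonia/ARDS`)       # anchor alone
  expect_false(roll("tachypnea")$`severe pneumonia/ARDS`)   # disjunct alone

  none <- roll(character(0))
  expect_false(any(unlist(none[, names(severity_group_map())])))

  bad_map <- list(x = list(features = "unicorn sign", rule = "any"))
  expect_error(severity_rollup(make_match("cough"), bad_map), "unicorn sign")
})
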