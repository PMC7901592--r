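test_that("an empty planting yields only seed roles", {
  cfg <- synth_embedding_config(c("fever", "cough"), dimension = 10,
                                synonyms_per_seed = 0, related_per_seed = 0,
                                distractor_count = 0, rng_seed = 1)
  sp <- generate_embedding_space(cfg)
  expect_identical(vocabulary(sp$source), c("fever", "cough"))
  expect_true(all(sp$truth$role == "seed"))
})

test_that("zero jitter forces the planted cosine exactly", {
  cfg <- synth_embedding_config("fever", dimension = 10,
                                synonyms_per_seed = 1, related_per_seed = 0,
                                distractor_count = 0,
                                target_cos_synonym = 0.95, cos_jitter = 0,
                                rng_seed = 2)
  sp <- generate_embedding_space(cfg)
  u <- sp$source$vectors["fever", ]
  v <- sp$source$vectors["fever_syn1", ]
  expect_equal(cosine_similarity(u, v), 0.95, tolerance = 1e-9)
})

test_that("planted cosines stay within the configured jitter band", {
  cfg <- synth_embedding_config(c("fever", "dry cough"), dimension = 30,
                                synonyms_per_seed = 4, related_per_seed = 3,
                                distractor_count = 20, cos_jitter = 0.05,
                                rng_seed = 3)
  sp <- generate_embedding_space(cfg)
  vecs <- sp$source$vectors
  planted <- sp$truth[sp$truth$role %in% c("synonym", "related"), ]
  seed_key <- gsub(" ", "_", tolower(planted$seed))
  for (i in seq_len(nrow(planted))) {
    got <- cosine_similarity(vecs[planted$term[i], ], vecs[seed_key[i], ])
    expect_lt(abs(got - planted$target_cosine[i]), 0.05 + 1e-9)
  }
  # distractors near-orthogonal to every seed by construction
  for (dterm in sp$truth$term[sp$truth$role == "distractor"]) {
    for (s in c("fever", "dry_cough")) {
      expect_lte(abs(cosine_similarity(vecs[dterm, ], vecs[s, ])), 0.3 + 1e-12)
    }
  }
})

test_that("top neighbours of each seed are exactly its planted synonyms", {
  cfg <- synth_embedding_config(c("fever", "hypoxia"), dimension = 50,
                                synonyms_per_seed = 5, related_per_seed = 5,
                                distractor_count = 50,
                                target_cos_synonym = 0.9,
                                target_cos_related = 0.4, rng_seed = 4)
  sp <- generate_embedding_space(cfg)
  for (seed in c("fever", "hypoxia")) {
    # oracle: brute-force full scan over the generated vocabulary
    oracle <- brute_force_neighbors(sp$source$vectors, seed, 5)
    expect_setequal(oracle$returned,
                    sp$truth$term[sp$truth$role == "synonym" &
                                    sp$truth$seed == seed])
    got <- top_k_neighbors(sp$source, seed, k = 5)
    expect_identical(got$returned, oracle$returned)
  }
})

test_that("generation is deterministic and validates its config", {
  cfg <- synth_embedding_config("fever", dimension = 12, rng_seed = 9,
                                distractor_count = 5)
  a <- generate_embedding_space(cfg)
  b <- generate_embedding_space(cfg)
  expect_identical(a$source$vectors, b$source$vectors)
  expect_identical(a$truth, b$truth)

  expect_error(synth_embedding_config("fever", dimension = 1), "at least 2")
  expect_error(synth_embedding_config(c("fever", "Fever"), dimension = 10),
               "unique")
  expect_error(synth_embedding_config("fever", target_cos_synonym = 0.3,
                                      target_cos_related = 0.4),
               "exceed")
  # too few dimensions to separate many seeds below |cos| 0.3
  squeezed <- synth_embedding_config(sprintf("s%d", 1:8), dimension = 2,
                                     distractor_count = 0, rng_seed = 1)
  expect_error(generate_embedding_space(squeezed), "could not place")
})

test_that("perfect and impossible agreement reproduce exactly", {
  cfg1 <- synth_annotation_config(50, agreement_prob = 1, rng_seed = 11)
  aset <- generate_annotation_set(cfg1)
  rep1 <- pairwise_agreement(aset$annotations, "by_query_term")
  expect_true(all(rep1$kappa == 1))

  # kernel that never returns the reference label
  labels <- semantic_types()
  K <- matrix(1 / 9, 10, 10, dimnames = list(labels, labels))
  diag(K) <- 0
  cfg0 <- synth_annotation_config(200, agreement_prob = 0,
                                  confusion_kernel = K, rng_seed = 12)
  aset0 <- generate_annotation_set(cfg0)
  ref <- aset0$reference$label
  for (a in cfg0$annotator_ids) {
    got <- aset0$annotations$label[aset0$annotations$annotator == a]
    expect_identical(mean(got == ref), 0)
  }
})

test_that("empirical kappa tracks the closed-form expectation", {
  cfg <- synth_annotation_config(4000, agreement_prob = 0.8, rng_seed = 13)
  exp_val <- expected_pairwise_agreement(cfg)
  # sanity on the enumeration itself: uniform base, symmetric kernel
  a <- 0.8
  p_same <- a^2 + (1 - a)^2 / 9          # both copy, or both err onto same label
  expect_equal(exp_val$p_o, p_same + 2 * a * 0, tolerance = 1e-12)
  expect_equal(exp_val$p_e, 0.1, tolerance = 1e-12)

  aset <- generate_annotation_set(cfg)
  rep <- pairwise_agreement(aset$annotations, "by_query_term")
  se <- sqrt(exp_val$p_o * (1 - exp_val$p_o) / cfg$item_count) / (1 - exp_val$p_e)
  expect_true(all(abs(rep$kappa - exp_val$kappa) < 3 * se))
})

test_that("annotation configs are validated", {
  expect_error(synth_annotation_config(0), "positive")
  expect_error(synth_annotation_config(5, annotator_ids = "A1"), "two distinct")
  expect_error(synth_annotation_config(5, agreement_prob = 1.5), "0, 1")
  labels <- semantic_types()
  badK <- matrix(0.2, 10, 10, dimnames = list(labels, labels))
  expect_error(synth_annotation_config(5, confusion_kernel = badK), "sum to 1")
  expect_error(synth_annotation_config(5, base_labels = c(synonym = 0.5)),
               "probability")
})

test_that("cohort notes plant terms at the configured prevalence", {
  lex <- toy_lexicon()
  cfg <- synth_cohort_config(
    cohorts = c(A = 60, B = 40),
    concept_prevalence = list(
      A = c(fever = 1.0, hypoxia = 0.0),
      B = c(fever = 0.5)
    ),
    notes_per_patient = 2, rng_seed = 21
  )
  corpus <- generate_cohort_notes(cfg, lex)
  expect_identical(nrow(corpus$notes), 200L)  # 100 patients x 2 notes
  props <- feature_proportions(match_features(corpus$notes, lex))
  expect_equal(props$proportion[props$cohort == "A" & props$concept == "fever"], 1)
  expect_equal(props$proportion[props$cohort == "A" & props$concept == "hypoxia"], 0)
  # unplanted concepts never appear
  expect_equal(props$proportion[props$concept == "malaise"], c(0, 0))
  # matching agrees with the generator's own truth record
  truth_fever <- corpus$truth[corpus$truth$concept == "fever", ]
  m <- match_features(corpus$notes, lex)
  got <- m$matched[m$concept == "fever"][match(truth_fever$patient_id,
                                               m$patient_id[m$concept == "fever"])]
  expect_identical(got, truth_fever$planted)
})

test_that("prevalence recovery converges at the binomial rate", {
  lex <- toy_lexicon()
  p <- 0.4
  n <- 1000
  cfg <- synth_cohort_config(
    cohorts = c(A = n),
    concept_prevalence = list(A = c(fever = p)),
    notes_per_patient = 2, rng_seed = 22
  )
  corpus <- generate_cohort_notes(cfg, lex)
  props <- feature_proportions(match_features(corpus$notes, lex))
  got <- props$proportion[props$concept == "fever"]
  expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("cohort generation rejects filler/lexicon collisions", {
  lex <- toy_lexicon()
  cfg <- synth_cohort_config(
    cohorts = c(A = 5),
    concept_prevalence = list(A = c(fever = 0.5)),
    filler_vocabulary = c("routine", "fever", "stable"),
    rng_seed = 23
  )
  expect_error(generate_cohort_notes(cfg, lex), "overlaps")
  expect_error(
    generate_cohort_notes(
      synth_cohort_config(cohorts = c(A = 5),
                          concept_prevalence = list(A = c(wheeze = 0.5)),
                          rng_seed = 23),
      lex
    ),
    "missing from lexicon"
  )
  expect_error(synth_cohort_config(cohorts = c(A = 5),
                                   concept_prevalence = list(A = c(f = 1.2))),
               "\\[0, 1\\]")
})

test_that("synthetic generators are reproducible under a fixed seed", {
  acfg <- synth_annotation_config(40, rng_seed = 31)
  expect_identical(generate_annotation_set(acfg), generate_annotation_set(acfg))
  ccfg <- synth_cohort_config(cohorts = c(A = 10),
                              concept_prevalence = list(A = c(fever = 0.5)),
                              rng_seed = 32)
  expect_identical(generate_cohort_notes(ccfg, toy_lexicon()),
                   generate_cohort_notes(ccfg, toy_lexicon()))
})
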